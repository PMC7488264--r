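#' Select the subset database of candidate genomes
#'
#' Keeps genomes whose containment estimate is at least `cutoff` (inclusive;
#' default 0.01, a deliberately liberal bound that trades a few extra
#' candidate genomes for very high recall — the alignment stage removes the
#' false positives). In `best_per_species` mode only the strain with the
#' highest containment is kept per species, ties broken by lexicographically
#' smallest `genome_id`; genomes without a species taxid are treated as their
#' own singleton species and never collapsed.
#'
#' @param results Tibble from [containment_table()] (columns `genome_id`,
#'   `species_taxid`, `containment_estimate`).
#' @param cutoff Containment threshold in `[0, 1]` (default 0.01).
#' @param strain_mode `"best_per_species"` (default) or `"all_strains"`.
#' @return A `subset_db` tibble (`genome_id`, `species_taxid`,
#'   `containment_estimate`), sorted by descending containment then
#'   `genome_id`, with attributes `cutoff` and `strain_mode`.
#' @export
select_subset <- function(results, cutoff = 0.01,
                          strain_mode = c("best_per_species", "all_strains")) {
  check_scalar_number(cutoff, "cutoff", 0, 1)
  strain_mode <- match.arg(strain_mode)
  sel <- results |>
    dplyr::filter(.data$containment_estimate >= cutoff) |>
    dplyr::select("genome_id", "species_taxid", "containment_estimate")
  if (strain_mode == "best_per_species" && nrow(sel) > 0) {
    # singleton "species" for genomes lacking a species taxid
    key <- ifelse(is.na(sel$species_taxid),
                  paste0("genome:", sel$genome_id),
                  paste0("species:", sel$species_taxid))
    sel <- sel |>
      dplyr::mutate(.key = key) |>
      dplyr::arrange(dplyr::desc(.data$containment_estimate), .data$genome_id) |>
      dplyr::distinct(.data$.key, .keep_all = TRUE) |>
      dplyr::select(-".key")
  }
  out <- dplyr::arrange(sel, dplyr::desc(.data$containment_estimate),
                        .data$genome_id)
  attr(out, "cutoff") <- cutoff
  attr(out, "strain_mode") <- strain_mode
  class(out) <- c("subset_db", class(out))
  out
}

#' Write the subset database as one multi-FASTA for alignment
#'
#' Concatenates the selected genomes' FASTA records into one file, prefixing
#' every record id with `<genome_id>|` so alignments are attributable to
#' genomes, and writes a sidecar TSV mapping `record_id` to `genome_id` and
#' `species_taxid`.
#'
#' @param subset A [select_subset()] tibble.
#' @param genome_paths Named character vector mapping `genome_id` to FASTA
#'   path.
#' @param out_fasta,out_tsv Output paths.
#' @return Invisibly, a list with `fasta`, `sidecar` paths and the sidecar
#'   tibble (`record_id`, `genome_id`, `species_taxid`).
#' @export
write_subset_fasta <- function(subset, genome_paths, out_fasta, out_tsv) {
  if (nrow(subset) == 0) {
    warn("empty subset database: writing an empty FASTA.")
    writeLines(character(), out_fasta)
    sidecar <- tibble(record_id = character(), genome_id = character(),
                      species_taxid = character())
    readr::write_tsv(sidecar, out_tsv)
    return(invisible(list(fasta = out_fasta, sidecar = out_tsv, map = sidecar)))
  }
  missing <- setdiff(subset$genome_id, names(genome_paths))
  if (length(missing) > 0) {
    abort(sprintf("no FASTA path for genome '%s'.", missing[1]),
          class = "sketchtax_io_error")
  }
  recs <- purrr::map(subset$genome_id, function(g) {
    seqs <- read_seq_file(genome_paths[[g]])
    names(seqs) <- paste0(g, "|", names(seqs))
    seqs
  })
  all_seqs <- unlist(recs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(all_seqs), out_fasta)
  sidecar <- tibble(
    record_id = names(all_seqs),
    genome_id = rep(subset$genome_id, lengths(recs)),
    species_taxid = rep(subset$species_taxid, lengths(recs))
  )
  readr::write_tsv(sidecar, out_tsv)
  invisible(list(fasta = out_fasta, sidecar = out_tsv, map = sidecar))
}

#' Read a subset sidecar TSV back into a record map
#'
#' @param path Sidecar TSV written by [write_subset_fasta()].
#' @return Tibble `record_id`, `genome_id`, `species_taxid`.
#' @export
read_subset_sidecar <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
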