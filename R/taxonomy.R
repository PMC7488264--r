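#' Load a genome taxonomy table
#'
#' The taxonomy format is a flat, versionable TSV with three pipe-delimited
#' columns per genome: `genome_id`, `taxids`, `names`, `ranks`, e.g.
#' `G1<TAB>2|1224|28211<TAB>Bacteria|Proteobacteria|Alphaproteobacteria<TAB>superkingdom|phylum|class`.
#' Ranks must be drawn from [cami_ranks()] and appear in canonical order;
#' missing intermediate ranks are permitted. An NCBI `nodes.dmp`/`names.dmp`
#' pair can be flattened to this format with a few lines of scripting; the
#' package deliberately consumes only the flat file.
#'
#' @param path Path to the taxonomy TSV (no header row).
#' @return A tidy tibble with one row per (genome, rank): columns
#'   `genome_id`, `taxid`, `name`, `rank`, `depth` (position of the rank in
#'   the canonical order).
#' @export
load_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warn(sprintf("taxonomy file '%s' is empty.", path))
    return(tibble(genome_id = character(), taxid = character(),
                  name = character(), rank = character(), depth = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed taxonomy row at line %d: expected 4 tab-separated columns.",
                  bad[1]),
          class = "sketchtax_parse_error")
  }
  rows <- purrr::imap(fields, function(f, i) {
    taxids <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    nms <- strsplit(f[3], "|", fixed = TRUE)[[1]]
    ranks <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    if (length(taxids) != length(nms) || length(taxids) != length(ranks)) {
      abort(sprintf("taxonomy line %d: taxid/name/rank lists differ in length.", i),
            class = "sketchtax_parse_error")
    }
    unknown <- setdiff(ranks, CAMI_RANKS)
    if (length(unknown) > 0) {
      abort(sprintf("taxonomy line %d: unknown rank label '%s'.", i, unknown[1]),
            class = "sketchtax_parse_error")
    }
    depth <- match(ranks, CAMI_RANKS)
    if (is.unsorted(depth, strictly = TRUE)) {
      abort(sprintf("taxonomy line %d: ranks out of canonical order.", i),
            class = "sketchtax_parse_error")
    }
    tibble(genome_id = f[1], taxid = taxids, name = nms, rank = ranks,
           depth = depth)
  })
  tax <- purrr::list_rbind(rows)
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate genome_id '%s' in taxonomy.", ids[duplicated(ids)][1]),
          class = "sketchtax_parse_error")
  }
  tax
}

#' Write a taxonomy tibble back to the flat TSV format
#'
#' @param taxonomy Tidy taxonomy tibble as returned by [load_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  rows <- taxonomy |>
    dplyr::arrange(.data$genome_id, .data$depth) |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      line = paste(.data$genome_id[1],
                   paste(.data$taxid, collapse = "|"),
                   paste(.data$name, collapse = "|"),
                   paste(.data$rank, collapse = "|"),
                   sep = "\t"),
      .groups = "drop"
    )
  writeLines(rows$line, path)
  invisible(path)
}

#' Look up a lineage's taxid at a given rank
#'
#' @param lineage Rows of the taxonomy tibble for one genome.
#' @param rank A canonical rank label.
#' @return The taxid at that rank, or `NA_character_` when the lineage has no
#'   entry at that rank.
#' @export
ancestor_at_rank <- function(lineage, rank) {
  if (!rank %in% CAMI_RANKS) {
    abort(sprintf("unknown rank '%s'.", rank),
          class = "sketchtax_invalid_parameter")
  }
  hit <- lineage$taxid[lineage$rank == rank]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

# Split a tidy taxonomy into a named list of per-genome lineages.
lineage_list <- function(taxonomy) {
  split(taxonomy, taxonomy$genome_id)
}
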