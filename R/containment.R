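#' Estimate the containment of a genome in a read sample
#'
#' The containment index C of genome A in sample B is the fraction of A's
#' distinct canonical k-mers that are present in B. It is estimated from the
#' genome's bottom-k MinHash sketch: `raw_hits / |sketch|`, the fraction of
#' sketch hashes whose k-mers test positive in the sample membership. With a
#' Bloom membership of false-positive rate p the estimate is corrected to
#' `(raw - p) / (1 - p)` and clamped to `[0, 1]`. An empty sketch yields 0.
#'
#' @param sketch A [build_sketch()] object.
#' @param sample A [build_sample_membership()] object with matching `k` and
#'   `hash_seed`.
#' @param species_taxid Optional species taxid carried through for strain
#'   collapsing (default `NA`).
#' @return A one-row tibble: `genome_id`, `species_taxid`, `raw_hits`,
#'   `sketch_len`, `containment_estimate`.
#' @export
estimate_containment <- function(sketch, sample, species_taxid = NA_character_) {
  stopifnot(inherits(sketch, "kmer_sketch"),
            inherits(sample, "sample_membership"))
  if (sketch$k != sample$k) {
    abort(sprintf("k mismatch: sketch k = %d, sample k = %d.",
                  sketch$k, sample$k),
          class = "sketchtax_invalid_parameter")
  }
  if (sketch$hash_seed != sample$hash_seed) {
    abort(sprintf("hash seed mismatch: sketch seed = %d, sample seed = %d.",
                  sketch$hash_seed, sample$hash_seed),
          class = "sketchtax_invalid_parameter")
  }
  s <- length(sketch$hashes)
  if (s == 0) {
    raw_hits <- 0L
    est <- 0
  } else {
    raw_hits <- sum(query_membership(sample, sketch$hashes))
    raw <- raw_hits / s
    p <- sample$bloom_fp_rate
    est <- if (p > 0) (raw - p) / (1 - p) else raw
    est <- min(1, max(0, est))
  }
  tibble(
    genome_id = sketch$genome_id,
    species_taxid = as.character(species_taxid),
    raw_hits = as.integer(raw_hits),
    sketch_len = s,
    containment_estimate = est
  )
}

#' Containment estimates for a whole sketch database
#'
#' @param sketches Named list of `kmer_sketch` objects.
#' @param sample A `sample_membership`.
#' @param taxonomy Optional taxonomy tibble from [load_taxonomy()]; when
#'   given, each genome's species taxid is attached (genomes without a
#'   species entry keep `NA` and are treated as singleton species
#'   downstream).
#' @return A tibble with one row per genome, sorted by descending
#'   `containment_estimate`.
#' @export
containment_table <- function(sketches, sample, taxonomy = NULL) {
  species <- rep(NA_character_, length(sketches))
  names(species) <- vapply(sketches, `[[`, "", "genome_id")
  if (!is.null(taxonomy)) {
    sp <- dplyr::filter(taxonomy, .data$rank == "species")
    species[sp$genome_id[sp$genome_id %in% names(species)]] <-
      sp$taxid[sp$genome_id %in% names(species)]
  }
  purrr::map2(sketches, species[names(species)], function(sk, tx) {
    estimate_containment(sk, sample, tx)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$containment_estimate), .data$genome_id)
}
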