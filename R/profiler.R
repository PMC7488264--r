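#' Count uniquely aligned reads per genome
#'
#' A read is uniquely aligned when, after the aligned-fraction filter and
#' genome-level deduplication, it hits exactly one genome. Unique reads are
#' the anchor of the profiler: they establish presence and set the weights
#' used to redistribute multi-aligned reads.
#'
#' @param assignments Per-read assignment tibble from [group_by_read()].
#' @return Tibble `genome_id`, `unique_reads`, `unique_bases` (aligned bases
#'   of uniquely assigned reads), one row per genome with unique evidence.
#' @export
count_unique <- function(assignments) {
  assignments |>
    dplyr::filter(.data$is_unique) |>
    dplyr::mutate(genome_id = vapply(.data$genomes, `[[`, "", 1)) |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      unique_reads = dplyr::n(),
      unique_bases = sum(.data$aligned_bases),
      .groups = "drop"
    )
}

#' Redistribution weights for one multi-aligned read
#'
#' A read aligned to several genomes has its abundance shared among them
#' proportionally to each genome's uniquely aligned read count. With unique
#' counts X = 6000 and Y = 2000, a read aligned to both contributes 75% of
#' its bases to X and 25% to Y. Genomes with no unique reads get weight 0; if
#' none of the read's genomes has unique evidence the weights are all 0 and
#' the read's mass is discarded.
#'
#' @param genomes Character vector of the genomes the read aligns to (>= 2).
#' @param unique_counts Named numeric vector (or [count_unique()] tibble) of
#'   unique read counts per genome.
#' @return Named numeric weights over `genomes`, summing to 1 (or all 0).
#' @export
multiread_weights <- function(genomes, unique_counts) {
  if (is.data.frame(unique_counts)) {
    unique_counts <- rlang::set_names(unique_counts$unique_reads,
                                      unique_counts$genome_id)
  }
  u <- unique_counts[genomes]
  u[is.na(u)] <- 0
  tot <- sum(u)
  w <- if (tot > 0) u / tot else rep(0, length(genomes))
  rlang::set_names(as.numeric(w), genomes)
}

#' Resolve multi-aligned reads proportionally to unique evidence
#'
#' Applies [multiread_weights()] to every multi-aligned read, splitting its
#' aligned-base mass across its genomes.
#'
#' @param assignments Per-read assignment tibble from [group_by_read()] (only
#'   rows with `is_unique == FALSE` are used).
#' @param unique_counts Named vector or [count_unique()] tibble.
#' @return Tibble `read_id`, `genome_id`, `shared_bases` with one row per
#'   (multi-read, genome) pair receiving positive or zero mass; reads whose
#'   genomes all lack unique evidence contribute rows with `shared_bases`
#'   0 and are effectively discarded.
#' @export
resolve_multimapped <- function(assignments, unique_counts) {
  if (is.data.frame(unique_counts)) {
    unique_counts <- rlang::set_names(unique_counts$unique_reads,
                                      unique_counts$genome_id)
  }
  multi <- dplyr::filter(assignments, !.data$is_unique)
  if (nrow(multi) == 0) {
    return(tibble(read_id = character(), genome_id = character(),
                  shared_bases = numeric()))
  }
  long <- multi |>
    dplyr::select("read_id", "genomes", "aligned_bases") |>
    tidyr::unnest_longer("genomes", values_to = "genome_id")
  u <- unname(unique_counts[long$genome_id])
  u[is.na(u)] <- 0
  long |>
    dplyr::mutate(.u = u) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::mutate(
      .tot = sum(.data$.u),
      shared_bases = ifelse(.data$.tot > 0,
                            .data$aligned_bases * .data$.u / .data$.tot, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("read_id", "genome_id", "shared_bases")
}

#' Accumulate per-genome abundance evidence
#'
#' Combines unique counts and redistributed multi-read mass into one evidence
#' table. `assigned_bases` (the abundance currency) is `unique_bases` plus
#' the genome's fractional shares of multi-aligned reads; with
#' `currency = "reads"` read counts are accumulated instead of bases.
#'
#' @param assignments Per-read assignment tibble from [group_by_read()].
#' @param currency `"bases"` (default) or `"reads"`.
#' @return Tibble `genome_id`, `unique_reads`, `unique_bases`,
#'   `assigned_bases` (includes genomes with zero unique reads but shared
#'   mass, which [apply_presence_rule()] removes).
#' @export
genome_evidence <- function(assignments, currency = c("bases", "reads")) {
  currency <- match.arg(currency)
  if (currency == "reads") {
    assignments <- dplyr::mutate(assignments, aligned_bases = 1)
  }
  uniq <- count_unique(assignments)
  shared <- resolve_multimapped(assignments, uniq) |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(shared_bases = sum(.data$shared_bases), .groups = "drop")
  dplyr::full_join(uniq, shared, by = "genome_id") |>
    tidyr::replace_na(list(unique_reads = 0L, unique_bases = 0,
                           shared_bases = 0)) |>
    dplyr::mutate(assigned_bases = .data$unique_bases + .data$shared_bases) |>
    dplyr::select("genome_id", "unique_reads", "unique_bases",
                  "assigned_bases") |>
    dplyr::arrange(.data$genome_id)
}

#' Apply the presence rule
#'
#' An organism is called present only if at least `min_unique_reads` reads
#' aligned uniquely to its genome; genomes below the threshold are removed
#' together with any multi-read mass already assigned to them (the mass is
#' dropped, not re-redistributed).
#'
#' @param evidence Tibble from [genome_evidence()].
#' @param min_unique_reads Minimum unique reads to call presence (default 1).
#' @return The filtered evidence tibble.
#' @export
apply_presence_rule <- function(evidence, min_unique_reads = 1L) {
  min_unique_reads <- check_count(min_unique_reads, "min_unique_reads")
  dplyr::filter(evidence, .data$unique_reads >= min_unique_reads)
}

# taxpath/taxpathsn for one lineage truncated at rank depth d, bridging
# missing interior ranks with empty fields (CAMI gap convention)
lineage_paths_at_depth <- function(lineage, d) {
  taxids <- names <- rep("", d)
  keep <- lineage$depth <= d
  taxids[lineage$depth[keep]] <- lineage$taxid[keep]
  names[lineage$depth[keep]] <- lineage$name[keep]
  nonempty <- which(taxids != "")
  if (length(nonempty) == 0) return(NULL)
  list(
    taxid = taxids[max(nonempty)],
    name = names[max(nonempty)],
    taxpath = paste(taxids, collapse = "|"),
    taxpathsn = paste(names, collapse = "|")
  )
}

#' Build a taxonomic profile from genome evidence
#'
#' Normalizes surviving genomes' assigned mass to relative abundances
#' (percentages summing to 100) and rolls them up the rank hierarchy: the
#' abundance at rank r of a taxon is the sum over present genomes whose
#' lineage passes through it. Genomes lacking an entry at a rank contribute
#' through their deepest available ancestor with empty taxpath fields at the
#' missing ranks.
#'
#' @param evidence Evidence tibble after [apply_presence_rule()].
#' @param taxonomy Tidy taxonomy tibble from [load_taxonomy()] covering every
#'   surviving genome.
#' @param ranks Ranks to emit; default all of [cami_ranks()] down to the
#'   deepest rank any surviving genome has.
#' @param sample_id Sample identifier stored in the profile.
#' @param unmapped_fraction Optional fraction of the sample (0--1) regarded
#'   as unmapped/novel; when > 0 percentages are scaled by
#'   `1 - unmapped_fraction` so rank sums fall below 100, acknowledging that
#'   part of the sample is not represented by any reference genome.
#' @return A `cami_profile` tibble: `rank`, `taxid`, `taxpath`, `taxpathsn`,
#'   `percentage`, with attributes `sample_id` and `ranks`.
#' @export
build_profile <- function(evidence, taxonomy, ranks = NULL,
                          sample_id = "sample", unmapped_fraction = 0) {
  check_scalar_number(unmapped_fraction, "unmapped_fraction", 0, 1)
  if (nrow(evidence) == 0) {
    return(new_cami_profile(
      tibble(rank = character(), taxid = character(), taxpath = character(),
             taxpathsn = character(), percentage = numeric()),
      sample_id = sample_id
    ))
  }
  lins <- lineage_list(taxonomy)
  missing <- setdiff(evidence$genome_id, names(lins))
  if (length(missing) > 0) {
    abort(sprintf("genome '%s' has no lineage in the taxonomy.", missing[1]),
          class = "sketchtax_invalid_parameter")
  }
  lins <- lins[evidence$genome_id]
  if (is.null(ranks)) {
    max_depth <- max(vapply(lins, function(l) max(l$depth), 0L))
    ranks <- CAMI_RANKS[seq_len(max_depth)]
  } else {
    stopifnot(all(ranks %in% CAMI_RANKS))
  }
  abundance <- evidence$assigned_bases / sum(evidence$assigned_bases) * 100 *
    (1 - unmapped_fraction)
  rows <- purrr::map(match(ranks, CAMI_RANKS), function(d) {
    per_genome <- purrr::imap(lins, function(l, g) {
      p <- lineage_paths_at_depth(l, d)
      if (is.null(p)) return(NULL)
      tibble(genome_id = g, taxid = p$taxid, taxpath = p$taxpath,
             taxpathsn = p$taxpathsn)
    })
    entries <- purrr::list_rbind(purrr::compact(per_genome))
    if (nrow(entries) == 0) return(NULL)
    entries$abundance <- abundance[match(entries$genome_id, evidence$genome_id)]
    entries |>
      dplyr::group_by(.data$taxpath) |>
      dplyr::summarise(
        rank = CAMI_RANKS[d],
        taxid = .data$taxid[1],
        taxpathsn = .data$taxpathsn[1],
        percentage = sum(.data$abundance),
        .groups = "drop"
      ) |>
      dplyr::select("rank", "taxid", "taxpath", "taxpathsn", "percentage")
  })
  prof <- purrr::list_rbind(purrr::compact(rows)) |>
    dplyr::arrange(match(.data$rank, CAMI_RANKS),
                   dplyr::desc(.data$percentage), .data$taxid)
  new_cami_profile(prof, sample_id = sample_id)
}

#' Remove low-abundance entries from a profile
#'
#' Drops, at every rank, entries whose percentage is strictly below
#' `min_percent`. By default the surviving entries keep their original
#' percentages (so rank sums may fall below 100, matching how profiles are
#' thresholded before evaluation); with `renormalize = TRUE` each rank is
#' rescaled to sum to 100 again.
#'
#' @param profile A `cami_profile`.
#' @param min_percent Abundance cutoff on the percentage scale (default 0.01,
#'   i.e. 0.01%).
#' @param renormalize Rescale each rank to 100 after the cutoff (default
#'   `FALSE`).
#' @return The filtered `cami_profile`.
#' @export
apply_abundance_cutoff <- function(profile, min_percent = 0.01,
                                   renormalize = FALSE) {
  check_scalar_number(min_percent, "min_percent", 0, Inf)
  out <- dplyr::filter(profile, .data$percentage >= min_percent)
  if (renormalize && nrow(out) > 0) {
    out <- out |>
      dplyr::group_by(.data$rank) |>
      dplyr::mutate(percentage = .data$percentage / sum(.data$percentage) * 100) |>
      dplyr::ungroup()
  }
  new_cami_profile(out, sample_id = profile_sample_id(profile))
}

#' Profile a filtered alignment table end to end
#'
#' Convenience wrapper running [group_by_read()], [genome_evidence()],
#' [apply_presence_rule()] and [build_profile()] in sequence.
#'
#' @param records Alignment tibble (already parsed; the `min_frac` filter is
#'   applied here).
#' @param taxonomy Tidy taxonomy tibble.
#' @param min_frac Aligned-fraction threshold (default 0.95).
#' @param min_unique_reads Presence threshold (default 1).
#' @param min_abundance Post-hoc abundance cutoff in percent (default 0).
#' @inheritParams build_profile
#' @inheritParams genome_evidence
#' @return A list with `profile` (`cami_profile`) and `evidence` (the
#'   per-genome tibble after the presence rule).
#' @export
profile_alignments <- function(records, taxonomy, min_frac = 0.95,
                               min_unique_reads = 1L, min_abundance = 0,
                               currency = "bases", ranks = NULL,
                               sample_id = "sample", unmapped_fraction = 0) {
  evidence <- records |>
    filter_alignments(min_frac) |>
    group_by_read() |>
    genome_evidence(currency = currency) |>
    apply_presence_rule(min_unique_reads)
  profile <- build_profile(evidence, taxonomy, ranks = ranks,
                           sample_id = sample_id,
                           unmapped_fraction = unmapped_fraction)
  if (min_abundance > 0) {
    profile <- apply_abundance_cutoff(profile, min_abundance)
  }
  list(profile = profile, evidence = evidence)
}
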