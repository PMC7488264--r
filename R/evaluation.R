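#' Compare a predicted profile against a truth profile at one rank
#'
#' Presence sets are the taxids with positive percentage at the requested
#' rank, after applying `abundance_cutoff` (percent) to the PREDICTED profile
#' only, mirroring how low-abundance false positives are thresholded before
#' evaluation. Metrics: precision = TP/(TP+FP), recall = TP/(TP+FN), F1 =
#' 2PR/(P+R), Jaccard = TP/(TP+FP+FN), and the L1 error = sum over the union
#' of taxids of |truth - predicted| with abundances as fractions (range
#' 0--2); the rescaled score 1 - L1/2 makes higher better. When both
#' presence sets are empty the set metrics are vacuously 1.
#'
#' @param truth,predicted `cami_profile` objects.
#' @param rank Rank to evaluate.
#' @param abundance_cutoff Percentage cutoff applied to `predicted` (default
#'   0).
#' @return One-row tibble: `rank`, `cutoff`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `jaccard`, `l1_error`, `l1_rescaled`.
#' @export
compare_profiles <- function(truth, predicted, rank, abundance_cutoff = 0) {
  if (!is.numeric(abundance_cutoff) || length(abundance_cutoff) != 1 ||
      is.na(abundance_cutoff) || abundance_cutoff < 0) {
    abort("`abundance_cutoff` must be a single non-negative number.",
          class = "sketchtax_invalid_parameter")
  }
  t_r <- dplyr::filter(as_tibble(truth), .data$rank == !!rank)
  p_r <- dplyr::filter(as_tibble(predicted), .data$rank == !!rank,
                       .data$percentage >= abundance_cutoff)
  t_set <- unique(t_r$taxid[t_r$percentage > 0])
  p_set <- unique(p_r$taxid[p_r$percentage > 0])
  tp <- length(intersect(t_set, p_set))
  fp <- length(setdiff(p_set, t_set))
  fn <- length(setdiff(t_set, p_set))
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  jaccard <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  all_tax <- union(t_set, union(unique(t_r$taxid), unique(p_r$taxid)))
  t_ab <- rlang::set_names(rep(0, length(all_tax)), all_tax)
  p_ab <- t_ab
  t_ab[t_r$taxid] <- t_r$percentage / 100
  p_ab[p_r$taxid] <- p_r$percentage / 100
  l1 <- sum(abs(t_ab - p_ab))
  tibble(
    rank = rank, cutoff = abundance_cutoff,
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1, jaccard = jaccard,
    l1_error = l1, l1_rescaled = 1 - l1 / 2
  )
}

#' Sweep the abundance cutoff and recompute metrics
#'
#' Recomputes [compare_profiles()] at each cutoff, leaving out predicted taxa
#' below the threshold. On communities whose true taxa all sit well above the
#' highest false-positive abundance, the sweep shows F1 reaching 1 once the
#' cutoff separates the two groups.
#'
#' @inheritParams compare_profiles
#' @param cutoffs Ascending numeric vector of percentage cutoffs.
#' @return A `cutoff_sweep` tibble with one row per cutoff.
#' @export
cutoff_sweep <- function(truth, predicted, rank, cutoffs) {
  stopifnot(is.numeric(cutoffs), !is.unsorted(cutoffs))
  out <- purrr::map(cutoffs, function(ct) {
    compare_profiles(truth, predicted, rank, abundance_cutoff = ct)
  }) |> purrr::list_rbind()
  class(out) <- c("cutoff_sweep", class(out))
  out
}
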