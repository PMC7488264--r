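#' Plot a taxonomic profile
#'
#' Horizontal bars of relative abundance, faceted by rank (deepest ranks can
#' be crowded; restrict with `ranks`).
#'
#' @param object A `cami_profile`.
#' @param ranks Ranks to show (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cami_profile <- function(object, ranks = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(ranks)) df <- dplyr::filter(df, .data$rank %in% ranks)
  df <- dplyr::mutate(
    df,
    rank = factor(.data$rank, levels = CAMI_RANKS),
    label = dplyr::coalesce(
      dplyr::na_if(vapply(strsplit(df$taxpathsn, "|", fixed = TRUE),
                          function(x) x[max(which(nzchar(x)))], ""), ""),
      .data$taxid
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$percentage,
    y = stats::reorder(.data$label, .data$percentage)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$rank), scales = "free_y") +
    ggplot2::labs(x = "relative abundance (%)", y = NULL,
                  title = sprintf("Taxonomic profile: %s",
                                  profile_sample_id(object))) +
    ggplot2::theme_minimal()
}

#' Plot metrics across an abundance-cutoff sweep
#'
#' @param object A [cutoff_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cutoff_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("cutoff", "precision", "recall", "f1", "l1_rescaled")],
    -"cutoff", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$cutoff, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "abundance cutoff (%)", y = "score", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot per-genome containment estimates against the selection cutoff
#'
#' @param containment Tibble from [containment_table()].
#' @param cutoff Containment cutoff drawn as a dashed line (default 0.01).
#' @return A ggplot object.
#' @export
plot_containment <- function(containment, cutoff = 0.01) {
  ggplot2::ggplot(containment, ggplot2::aes(
    x = .data$containment_estimate,
    y = stats::reorder(.data$genome_id, .data$containment_estimate)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "containment estimate", y = NULL) +
    ggplot2::theme_minimal()
}
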