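CAMI_VERSION <- "0.9.1"

#' Construct a CAMI profile object
#'
#' A `cami_profile` is a tibble with columns `rank`, `taxid`, `taxpath`,
#' `taxpathsn`, `percentage` (0--100) and attributes `sample_id` and `ranks`
#' (the declared rank hierarchy). Most users will obtain one from
#' [build_profile()] or [read_cami_profile()].
#'
#' @param x Tibble with the five profile columns.
#' @param sample_id Sample identifier.
#' @param ranks Declared rank hierarchy (default [cami_ranks()]).
#' @return A `cami_profile`.
#' @export
new_cami_profile <- function(x, sample_id = "sample", ranks = cami_ranks()) {
  x <- as_tibble(x)[, c("rank", "taxid", "taxpath", "taxpathsn", "percentage")]
  attr(x, "sample_id") <- sample_id
  attr(x, "ranks") <- ranks
  class(x) <- c("cami_profile", class(x))
  x
}

profile_sample_id <- function(profile) {
  attr(profile, "sample_id") %||% "sample"
}

#' Write a profile in the CAMI/bioboxes profiling format
#'
#' Emits the `@SampleID`, `@Version` and `@Ranks` headers followed by the
#' `@@TAXID RANK TAXPATH TAXPATHSN PERCENTAGE` column line and tab-separated
#' rows ordered by rank depth then descending percentage, with percentages
#' printed to 6 decimal places.
#'
#' @param profile A `cami_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cami_profile <- function(profile, path) {
  ranks <- attr(profile, "ranks") %||% cami_ranks()
  ord <- order(match(profile$rank, ranks), -profile$percentage, profile$taxid)
  p <- profile[ord, ]
  lines <- c(
    paste0("@SampleID:", profile_sample_id(profile)),
    paste0("@Version:", CAMI_VERSION),
    paste0("@Ranks:", paste(ranks, collapse = "|")),
    "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
    sprintf("%s\t%s\t%s\t%s\t%.6f",
            p$taxid, p$rank, p$taxpath, p$taxpathsn, p$percentage)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a CAMI/bioboxes profile
#'
#' Tolerant reader: header keys are case-insensitive, blank lines and `#`
#' comments are skipped, but a missing `@Ranks` header or a row whose rank is
#' not declared there is rejected with the offending line number.
#'
#' @param path Path to a CAMI-format profile.
#' @return A `cami_profile`.
#' @export
read_cami_profile <- function(path) {
  lines <- readLines(path)
  sample_id <- "sample"
  ranks <- NULL
  rows <- list()
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i], which = "right")
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@@")) { seen_header <- TRUE; next }
    if (startsWith(line, "@")) {
      kv <- sub("^@", "", line)
      key <- tolower(sub(":.*$", "", kv))
      val <- sub("^[^:]*:", "", kv)
      if (key == "sampleid") sample_id <- trimws(val)
      if (key == "ranks") ranks <- strsplit(trimws(val), "|", fixed = TRUE)[[1]]
      next
    }
    if (is.null(ranks)) {
      abort(sprintf("line %d: profile data before the @Ranks header.", i),
            class = "sketchtax_parse_error")
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      abort(sprintf("line %d: expected 5 tab-separated profile columns.", i),
            class = "sketchtax_parse_error")
    }
    if (!f[2] %in% ranks) {
      abort(sprintf("line %d: rank '%s' not declared in @Ranks.", i, f[2]),
            class = "sketchtax_parse_error")
    }
    rows[[length(rows) + 1]] <- tibble(
      rank = f[2], taxid = f[1], taxpath = f[3], taxpathsn = f[4],
      percentage = as.numeric(f[5])
    )
  }
  if (is.null(ranks)) {
    abort("missing @Ranks header line.", class = "sketchtax_parse_error")
  }
  prof <- if (length(rows) > 0) {
    purrr::list_rbind(rows)
  } else {
    tibble(rank = character(), taxid = character(), taxpath = character(),
           taxpathsn = character(), percentage = numeric())
  }
  new_cami_profile(prof, sample_id = sample_id, ranks = ranks)
}

#' @export
print.cami_profile <- function(x, ...) {
  shown <- if ("rank" %in% names(x)) {
    paste(unique(x[["rank"]]), collapse = ", ")
  } else "?"
  cat(sprintf("# CAMI profile for sample '%s' (%d entries, ranks: %s)\n",
              profile_sample_id(x), nrow(x), shown))
  NextMethod()
}

#' @describeIn new_cami_profile `tidy()` returns the profile as a plain
#'   tibble.
#' @param ... Unused.
#' @export
tidy.cami_profile <- function(x, ...) {
  as_tibble(x) |> dplyr::mutate(sample_id = profile_sample_id(x), .before = 1)
}

#' @describeIn new_cami_profile `glance()` returns a one-row per-rank summary
#'   (taxon counts and percentage totals).
#' @export
glance.cami_profile <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(n_taxa = dplyr::n(), total_percent = sum(.data$percentage),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$rank, CAMI_RANKS))
}
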