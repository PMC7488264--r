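#' Parse SAM or PAF alignments into a tidy alignment table
#'
#' Reads an alignment file of sample reads against the subset database and
#' computes, per alignment line, the number of read bases consumed by
#' alignment-match operations and the aligned fraction of the read.
#'
#' For SAM, `aligned_bases` is the sum of `M`/`=`/`X` CIGAR operation lengths
#' (query-side) and `read_length` the full query length (`M/I/S/=/X` plus
#' hard clips); unmapped records (flag 0x4 or `*` reference) are skipped and
#' secondary/supplementary alignments are kept, since multi-alignment is the
#' point. For PAF, `aligned_bases` is approximated by `query_end -
#' query_start` and `read_length` is column 2.
#'
#' @param path SAM or PAF file.
#' @param record_map Tibble mapping `record_id` to `genome_id` (the subset
#'   sidecar from [write_subset_fasta()]), or a named character vector; `NULL`
#'   uses reference names as genome ids unchanged.
#' @param format `"sam"` or `"paf"`; default guessed from the file extension.
#' @return Tibble with columns `read_id`, `genome_id`, `read_length`,
#'   `aligned_bases`, `frac_aligned`.
#' @export
parse_alignments <- function(path, record_map = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.paf(\\.gz)?$", path)) "paf" else "sam"
  }
  format <- match.arg(format, c("sam", "paf"))
  lines <- readLines(path)
  aln <- if (format == "sam") parse_sam_lines(lines) else parse_paf_lines(lines)
  if (!is.null(record_map)) {
    map <- if (is.data.frame(record_map)) {
      rlang::set_names(record_map$genome_id, record_map$record_id)
    } else {
      record_map
    }
    unknown <- setdiff(unique(aln$genome_id), names(map))
    if (length(unknown) > 0) {
      abort(sprintf("alignment references unknown record id '%s'.", unknown[1]),
            class = "sketchtax_parse_error")
    }
    aln$genome_id <- unname(map[aln$genome_id])
  }
  aln
}

# query-side CIGAR arithmetic: ops consuming the query are M I S = X (plus H
# for the physical read length)
cigar_query_stats <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  parsed_len <- vapply(ops, function(m) sum(nchar(m[, 1])), 0)
  if (any(parsed_len != nchar(cigar))) {
    i <- which(parsed_len != nchar(cigar))[1]
    abort(sprintf("unparseable CIGAR '%s' (unknown opcode?).", cigar[i]),
          class = "sketchtax_parse_error")
  }
  lens <- lapply(ops, function(m) as.numeric(m[, 2]))
  opch <- lapply(ops, function(m) m[, 3])
  aligned <- vapply(seq_along(ops), function(i) {
    sum(lens[[i]][opch[[i]] %in% c("M", "=", "X")])
  }, 0)
  read_len <- vapply(seq_along(ops), function(i) {
    sum(lens[[i]][opch[[i]] %in% c("M", "I", "S", "=", "X", "H")])
  }, 0)
  list(aligned_bases = aligned, read_length = read_len)
}

parse_sam_lines <- function(lines) {
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), genome_id = character(),
                  read_length = numeric(), aligned_bases = numeric(),
                  frac_aligned = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    abort("malformed SAM line: fewer than 11 fields.",
          class = "sketchtax_parse_error")
  }
  qname <- vapply(fields, `[[`, "", 1)
  flag <- as.integer(vapply(fields, `[[`, "", 2))
  rname <- vapply(fields, `[[`, "", 3)
  cigar <- vapply(fields, `[[`, "", 6)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*" & cigar != "*"
  qname <- qname[mapped]; rname <- rname[mapped]; cigar <- cigar[mapped]
  if (length(qname) == 0) {
    return(tibble(read_id = character(), genome_id = character(),
                  read_length = numeric(), aligned_bases = numeric(),
                  frac_aligned = numeric()))
  }
  st <- cigar_query_stats(cigar)
  tibble(
    read_id = qname,
    genome_id = rname,
    read_length = st$read_length,
    aligned_bases = st$aligned_bases,
    frac_aligned = st$aligned_bases / st$read_length
  )
}

parse_paf_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), genome_id = character(),
                  read_length = numeric(), aligned_bases = numeric(),
                  frac_aligned = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12)) {
    abort("malformed PAF line: fewer than 12 fields.",
          class = "sketchtax_parse_error")
  }
  read_len <- as.numeric(vapply(fields, `[[`, "", 2))
  qstart <- as.numeric(vapply(fields, `[[`, "", 3))
  qend <- as.numeric(vapply(fields, `[[`, "", 4))
  rname <- vapply(fields, `[[`, "", 6)
  keep <- rname != "*"
  tibble(
    read_id = vapply(fields, `[[`, "", 1)[keep],
    genome_id = rname[keep],
    read_length = read_len[keep],
    aligned_bases = (qend - qstart)[keep],
    frac_aligned = ((qend - qstart) / read_len)[keep]
  )
}

#' Filter alignments by aligned-base fraction
#'
#' Keeps alignments covering at least `min_frac` of the read's bases
#' (inclusive). The default 0.95 discards poor alignments while tolerating a
#' few errors, so a read's surviving alignments are all of comparable
#' quality.
#'
#' @param records Alignment tibble from [parse_alignments()].
#' @param min_frac Minimum aligned fraction in `[0, 1]` (default 0.95).
#' @return The filtered tibble.
#' @export
filter_alignments <- function(records, min_frac = 0.95) {
  check_scalar_number(min_frac, "min_frac", 0, 1)
  dplyr::filter(records, .data$frac_aligned >= min_frac)
}

#' Group passing alignments into per-read assignment sets
#'
#' Deduplicates alignments at the genome level (several alignments of one
#' read to one genome count once) and classifies each read as uniquely
#' aligned (exactly one genome) or multi-aligned. Input order is irrelevant.
#' A read's aligned-base mass is the maximum passing `aligned_bases` over its
#' alignments.
#'
#' @param records Filtered alignment tibble.
#' @return Tibble with one row per read: `read_id`, `genomes` (list column of
#'   distinct genome ids, sorted), `n_genomes`, `aligned_bases` (the read's
#'   mass), `is_unique`.
#' @export
group_by_read <- function(records) {
  records |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      genomes = list(sort(unique(.data$genome_id))),
      n_genomes = length(unique(.data$genome_id)),
      aligned_bases = max(.data$aligned_bases),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_unique = .data$n_genomes == 1L)
}
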