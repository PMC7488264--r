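#' Ungapped seed-and-verify toy aligner
#'
#' A deliberately simple aligner for fixture-scale data: every `k_seed`-mer
#' position of the subset database is indexed exactly; each read contributes
#' seeds at its start, middle and end (both orientations), and every seed hit
#' is verified by ungapped comparison of the read against the reference at
#' the implied offset. An alignment is reported for every reference record
#' where the identity over the read reaches `min_identity`, so reads from
#' near-identical strains produce multiple alignment lines. CIGARs are of the
#' form `<clip>S<match>M<clip>S` (substitution-only model: no indels, which
#' a production aligner such as minimap2 would handle).
#'
#' @param reads FASTQ/FASTA path or a named character vector of read
#'   sequences.
#' @param subset_fasta Multi-FASTA of the subset database (record ids as
#'   written by [write_subset_fasta()]).
#' @param k_seed Exact seed length (default 16).
#' @param min_identity Minimum matching fraction of the read (default 0.9).
#' @param out_sam Output SAM path.
#' @return `out_sam`, invisibly.
#' @export
toy_align <- function(reads, subset_fasta, k_seed = 16L, min_identity = 0.9,
                      out_sam = tempfile(fileext = ".sam")) {
  k_seed <- check_count(k_seed, "k_seed")
  check_scalar_number(min_identity, "min_identity", 0, 1)
  if (is.character(reads) && length(reads) == 1 && is.null(names(reads))) {
    reads <- read_seq_file(reads)
  }
  refs <- if (file.info(subset_fasta)$size == 0) character(0) else read_seq_file(subset_fasta)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  if (length(reads) == 0 || length(refs) == 0) {
    writeLines(header, out_sam)
    return(invisible(out_sam))
  }

  # index every seed position of every reference record
  idx <- purrr::imap(refs, function(s, rec) {
    n <- nchar(s) - k_seed + 1L
    if (n < 1) return(NULL)
    tibble(kmer = substring(s, 1:n, k_seed:(n + k_seed - 1L)),
           record = rec, rpos = 1:n)
  })
  idx <- purrr::list_rbind(purrr::compact(idx))

  rl <- nchar(reads)
  rc <- revcomp(reads)
  offs_of <- function(len) unique(pmax(1L, c(1L, (len - k_seed) %/% 2L + 1L,
                                             len - k_seed + 1L)))
  # seeds from both orientations
  seed_tbl <- purrr::list_rbind(purrr::map(c("+", "-"), function(strand) {
    oriented <- if (strand == "+") reads else rc
    purrr::list_rbind(purrr::map(unique(rl), function(len) {
      sel <- which(rl == len & len >= k_seed)
      if (length(sel) == 0) return(NULL)
      purrr::list_rbind(purrr::map(offs_of(len), function(off) {
        tibble(read_idx = sel, strand = strand, off = off,
               kmer = substring(oriented[sel], off, off + k_seed - 1L))
      }))
    }))
  }))
  cand <- dplyr::inner_join(seed_tbl, idx, by = "kmer",
                            relationship = "many-to-many") |>
    dplyr::mutate(start = .data$rpos - .data$off + 1L) |>
    dplyr::distinct(.data$read_idx, .data$strand, .data$record, .data$start)
  if (nrow(cand) == 0) {
    writeLines(header, out_sam)
    return(invisible(out_sam))
  }

  ref_len <- nchar(refs)
  len <- rl[cand$read_idx]
  ref_from <- pmax(cand$start, 1L)
  ref_to <- pmin(cand$start + len - 1L, ref_len[cand$record])
  keep <- ref_to - ref_from + 1L >= k_seed
  cand <- cand[keep, ]; len <- len[keep]
  ref_from <- ref_from[keep]; ref_to <- ref_to[keep]
  oriented <- ifelse(cand$strand == "+", reads[cand$read_idx], rc[cand$read_idx])
  q_from <- ref_from - cand$start + 1L
  q_to <- ref_to - cand$start + 1L
  matches <- cpp_match_count(substring(oriented, q_from, q_to),
                             substring(refs[cand$record], ref_from, ref_to))
  hits <- cand |>
    dplyr::mutate(matches = matches, identity = matches / len,
                  q_from = q_from, q_to = q_to, len = len,
                  pos = ref_from) |>
    dplyr::filter(.data$identity >= min_identity) |>
    # best placement per (read, record, strand)
    dplyr::arrange(dplyr::desc(.data$matches)) |>
    dplyr::distinct(.data$read_idx, .data$record, .data$strand,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$read_idx, dplyr::desc(.data$matches))
  if (nrow(hits) == 0) {
    writeLines(header, out_sam)
    return(invisible(out_sam))
  }

  left_clip <- hits$q_from - 1L
  right_clip <- hits$len - hits$q_to
  m_len <- hits$q_to - hits$q_from + 1L
  cigar <- paste0(ifelse(left_clip > 0, paste0(left_clip, "S"), ""),
                  m_len, "M",
                  ifelse(right_clip > 0, paste0(right_clip, "S"), ""))
  primary <- !duplicated(hits$read_idx)
  flag <- ifelse(hits$strand == "-", 16L, 0L) + ifelse(primary, 0L, 256L)
  oriented_hit <- ifelse(hits$strand == "+", reads[hits$read_idx],
                         rc[hits$read_idx])
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  names(reads)[hits$read_idx], flag, hits$record, hits$pos,
                  cigar, oriented_hit)
  writeLines(c(header, body), out_sam)
  invisible(out_sam)
}
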