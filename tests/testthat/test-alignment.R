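sam_line <- function(qname, flag, rname, cigar, seq = "*") {
  paste(qname, flag, rname, 1, 60, cigar, "*", 0, 0, seq, "*", sep = "\t")
}

write_sam <- function(lines, refs = c("ref1", "ref2")) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:10000", refs), lines),
             path)
  path
}

test_that("aligned bases come from M/=/X CIGAR operations on the query", {
  path <- write_sam(c(
    sam_line("r1", 0, "ref1", "95M5S"),
    sam_line("r2", 4, "*", "*"),            # unmapped: skipped
    sam_line("r3", 16, "ref2", "10S80M10S"),
    sam_line("r4", 256, "ref1", "50=25X25S")
  ))
  aln <- parse_alignments(path)
  expect_identical(aln$read_id, c("r1", "r3", "r4"))
  expect_equal(aln$aligned_bases, c(95, 80, 75))
  expect_equal(aln$read_length, c(100, 100, 100))
  expect_equal(aln$frac_aligned, c(0.95, 0.80, 0.75))
})

test_that("CIGAR arithmetic agrees with GenomicAlignments on random CIGARs", {
  set.seed(51)
  ops <- c("M", "I", "D", "S", "=", "X", "N", "H")
  cigars <- vapply(1:50, function(i) {
    n <- sample(1:6, 1)
    paste0(sample(1:50, n, TRUE), sample(ops, n, TRUE), collapse = "")
  }, "")
  got <- sketchtax:::cigar_query_stats(cigars)
  tab <- GenomicAlignments::cigarOpTable(cigars)
  expect_equal(got$aligned_bases,
               unname(rowSums(tab[, c("M", "=", "X"), drop = FALSE])))
  expect_equal(got$read_length,
               unname(rowSums(tab[, c("M", "I", "S", "=", "X", "H"), drop = FALSE])))
  # and with the character-walking oracle
  oracle <- t(vapply(cigars, oracle_cigar_stats, c(aligned = 0, read_length = 0)))
  expect_equal(got$aligned_bases, unname(oracle[, "aligned"]))
  expect_equal(got$read_length, unname(oracle[, "read_length"]))
})

test_that("unknown CIGAR opcodes and unknown reference records are errors", {
  path <- write_sam(sam_line("r1", 0, "ref1", "50M2B"))
  expect_error(parse_alignments(path), class = "sketchtax_parse_error")
  path2 <- write_sam(sam_line("r1", 0, "refX", "50M"))
  map <- tibble::tibble(record_id = c("ref1", "ref2"),
                        genome_id = c("gA", "gB"))
  expect_error(parse_alignments(path2, map), "refX",
               class = "sketchtax_parse_error")
  aln <- parse_alignments(write_sam(sam_line("r1", 0, "ref2", "50M")), map)
  expect_identical(aln$genome_id, "gB")
})

test_that("PAF alignments approximate aligned bases by the query block", {
  path <- tempfile(fileext = ".paf")
  writeLines(c(
    paste("r1", 100, 0, 95, "+", "gA", 5000, 10, 105, 90, 95, 60, sep = "\t"),
    paste("r2", 150, 10, 150, "-", "gB", 5000, 10, 150, 120, 140, 60, sep = "\t")
  ), path)
  aln <- parse_alignments(path)
  expect_equal(aln$aligned_bases, c(95, 140))
  expect_equal(aln$frac_aligned, c(0.95, 140 / 150))
})

test_that("the 95% filter is inclusive at the boundary", {
  recs <- tibble::tibble(
    read_id = c("a", "b"), genome_id = "g", read_length = 100,
    aligned_bases = c(95, 94), frac_aligned = c(0.95, 0.94)
  )
  kept <- filter_alignments(recs, 0.95)
  expect_identical(kept$read_id, "a")
  expect_equal(nrow(filter_alignments(recs, 0)), 2)    # identity filter
  expect_equal(nrow(filter_alignments(recs, 1)), 0)    # only perfect spans
})

test_that("grouping dedupes genomes and matches a dictionary oracle", {
  recs <- tibble::tibble(
    read_id = c("r1", "r2", "r2", "r2"),
    genome_id = c("G1", "G1", "G1", "G2"),
    read_length = 100,
    aligned_bases = c(100, 98, 97, 99),
    frac_aligned = c(1, 0.98, 0.97, 0.99)
  )
  grp <- group_by_read(recs)
  expect_true(grp$is_unique[grp$read_id == "r1"])
  r2 <- grp[grp$read_id == "r2", ]
  expect_identical(r2$genomes[[1]], c("G1", "G2"))
  expect_false(r2$is_unique)
  expect_equal(r2$aligned_bases, 99)

  # random table, order invariance and brute-force dictionary pass
  set.seed(52)
  n <- 300
  recs <- tibble::tibble(
    read_id = sprintf("r%03d", sample(60, n, TRUE)),
    genome_id = sprintf("G%d", sample(8, n, TRUE)),
    read_length = 100,
    aligned_bases = sample(80:100, n, TRUE)
  )
  recs$frac_aligned <- recs$aligned_bases / recs$read_length
  grp <- group_by_read(recs)
  shuf <- group_by_read(recs[sample(n), ])
  expect_equal(as.data.frame(dplyr::arrange(grp, read_id)),
               as.data.frame(dplyr::arrange(shuf, read_id)))
  dict <- new.env()
  for (i in seq_len(n)) {
    key <- recs$read_id[i]
    cur <- if (!is.null(dict[[key]])) dict[[key]] else character(0)
    dict[[key]] <- union(cur, recs$genome_id[i])
  }
  expect_equal(nrow(grp), length(ls(dict)))
  for (key in ls(dict)) {
    expect_setequal(grp$genomes[grp$read_id == key][[1]], dict[[key]])
  }
})
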