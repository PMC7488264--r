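test_that("a single-species community is 100% at every rank of its lineage", {
  comm <- generate_community(community_spec(n_species = 1, genome_length = 500,
                                            abundances = 1, seed = 2))
  expect_true(all(abs(comm$truth$percentage - 100) < 1e-9))
  expect_equal(nchar(comm$genomes[[1]]), 500)
})

test_that("zero strain divergence copies the parent genome byte for byte", {
  comm <- generate_community(community_spec(
    n_species = 2, strains_per_species = 2, genome_length = 300,
    strain_divergence = 0, abundances = rep(0.25, 4), seed = 3
  ))
  expect_identical(comm$genomes[["sp01_st1"]], comm$genomes[["sp01_st2"]])
  pos <- generate_community(community_spec(
    n_species = 1, strains_per_species = 2, genome_length = 2000,
    strain_divergence = 0.01, abundances = c(0.5, 0.5), seed = 3
  ))
  expect_false(identical(pos$genomes[["sp01_st1"]], pos$genomes[["sp01_st2"]]))
})

test_that("equal seeds give byte-identical community outputs", {
  spec <- community_spec(n_species = 3, genome_length = 400, seed = 17)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_community(spec, d1)
  c2 <- generate_community(spec, d2)
  expect_identical(c1$genomes, c2$genomes)
  for (g in names(c1$genome_paths)) {
    expect_identical(readLines(c1$genome_paths[[g]]),
                     readLines(c2$genome_paths[[g]]))
  }
  expect_identical(readLines(c1$truth_path), readLines(c2$truth_path))
  expect_identical(readLines(c1$taxonomy_path), readLines(c2$taxonomy_path))
})

test_that("error-free reads are exact genome substrings in expected numbers", {
  comm <- generate_community(community_spec(
    n_species = 1, genome_length = 1e4, abundances = 1, coverage = 10,
    read_length = 100, error_rate = 0, seed = 4
  ))
  rd <- sample_reads(comm)
  expect_equal(rd$n_reads, 1000)  # 10x * 10 kb / 100 bp
  reads <- read_cami <- readLines(rd$fastq)
  seqs <- reads[seq(2, length(reads), 4)]
  g <- comm$genomes[[1]]
  fwd <- vapply(seqs, function(s) grepl(s, g, fixed = TRUE), TRUE)
  rev <- vapply(seqs, function(s) grepl(revcomp_str(s), g, fixed = TRUE), TRUE)
  expect_true(all(fwd | rev))
  expect_true(any(fwd) && any(rev))  # both strands sampled
  # origin table matches
  expect_equal(nrow(rd$origins), 1000)
  expect_true(all(rd$origins$genome_id == "sp01"))
})

test_that("read counts split by abundance within binomial tolerance", {
  comm <- generate_community(community_spec(
    n_species = 2, genome_length = 1e4, abundances = c(0.75, 0.25),
    coverage = 20, error_rate = 0, seed = 5
  ))
  rd <- sample_reads(comm)
  counts <- table(rd$origins$genome_id)
  expect_equal(unname(counts["sp01"] / sum(counts)), 0.75, tolerance = 0.02)
  # deterministic re-run
  rd2 <- sample_reads(comm)
  expect_identical(readLines(rd$fastq), readLines(rd2$fastq))
})

test_that("invalid community specs are rejected by field", {
  expect_error(community_spec(abundances = c(0.5, 0.4)),
               class = "sketchtax_invalid_parameter")
  expect_error(community_spec(n_species = 0),
               class = "sketchtax_invalid_parameter")
  expect_error(community_spec(error_rate = 1),
               class = "sketchtax_invalid_parameter")
  comm <- generate_community(community_spec(n_species = 1, genome_length = 50,
                                            abundances = 1, seed = 1))
  comm$spec$read_length <- 100L
  expect_error(sample_reads(comm), class = "sketchtax_invalid_parameter")
})

test_that("the toy aligner reports exact reads with full-length CIGARs", {
  set.seed(81)
  g <- random_dna(5000)
  fa <- write_fasta(c(`gA|rec1` = g))
  start <- 1001
  read <- substr(g, start, start + 99)
  sam <- toy_align(c(r1 = read), fa)
  aln <- parse_alignments(sam)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$aligned_bases, 100)
  expect_equal(aln$frac_aligned, 1)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_match(body, "\t100M\t")
  expect_match(body, sprintf("\t%d\t60\t", start))
  # reverse-strand read is found and flagged
  sam_rc <- toy_align(c(r1 = revcomp_str(read)), fa)
  body_rc <- readLines(sam_rc)
  body_rc <- body_rc[!startsWith(body_rc, "@")]
  expect_equal(as.integer(strsplit(body_rc, "\t")[[1]][2]), 16L)
})

test_that("reads from unrelated genomes produce no alignments", {
  set.seed(82)
  fa <- write_fasta(c(`gA|rec1` = random_dna(4000)))
  reads <- rlang::set_names(vapply(1:20, function(i) random_dna(100), ""),
                            sprintf("r%02d", 1:20))
  sam <- toy_align(reads, fa)
  expect_equal(nrow(parse_alignments(sam)), 0)
})

test_that("near-identical strains multi-align most reads", {
  comm <- generate_community(community_spec(
    n_species = 1, strains_per_species = 2, genome_length = 2e4,
    strain_divergence = 0.001, abundances = c(0.6, 0.4), coverage = 10,
    seed = 6
  ))
  rd <- sample_reads(comm)
  sub <- select_subset(
    tibble::tibble(genome_id = comm$genome_ids,
                   species_taxid = "70001",
                   containment_estimate = c(1, 1)),
    cutoff = 0, strain_mode = "all_strains"
  )
  out <- write_subset_fasta(sub, comm$genome_paths,
                            tempfile(fileext = ".fa"),
                            tempfile(fileext = ".tsv"))
  sam <- toy_align(rd$fastq, out$fasta)
  grp <- parse_alignments(sam, out$map) |>
    filter_alignments() |>
    group_by_read()
  expect_gte(mean(!grp$is_unique), 0.5)
})
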