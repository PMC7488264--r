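test_that("unique read counting sums reads and aligned bases per genome", {
  asg <- make_assignments(
    c("r1", "r2", "r3", "r4"),
    list("G1", "G1", "G1", c("G1", "G2")),
    c(100, 100, 100, 95)
  )
  uniq <- count_unique(asg)
  expect_equal(uniq$unique_reads, 3L)
  expect_equal(uniq$unique_bases, 300)
  none <- count_unique(make_assignments("r1", list(c("A", "B")), 90))
  expect_equal(nrow(none), 0)
})

test_that("multi-read weights are proportional to unique read counts", {
  w <- multiread_weights(c("X", "Y"), c(X = 6000, Y = 2000))
  expect_equal(unname(w), c(0.75, 0.25))
  expect_equal(sum(w), 1)
  w2 <- multiread_weights(c("X", "Y"), c(X = 5000, Y = 0))
  expect_equal(unname(w2), c(1, 0))
  w3 <- multiread_weights(c("A", "B", "C"), c(A = 1, B = 1, C = 2))
  expect_equal(unname(w3) * 100, c(25, 25, 50))
  # all genomes lacking unique evidence: weights all zero (mass discarded)
  w0 <- multiread_weights(c("A", "B"), c(Z = 10))
  expect_equal(unname(w0), c(0, 0))
})

test_that("redistribution conserves mass for reads with unique evidence", {
  set.seed(61)
  genomes <- sprintf("G%d", 1:6)
  uniq <- rlang::set_names(c(40, 25, 10, 5, 0, 0), genomes)
  n <- 200
  asg <- make_assignments(
    sprintf("m%03d", 1:n),
    replicate(n, sample(genomes, sample(2:4, 1)), simplify = FALSE),
    sample(90:100, n, TRUE)
  )
  shares <- resolve_multimapped(asg, uniq)
  per_read <- tapply(shares$shared_bases, shares$read_id, sum)
  for (i in seq_len(n)) {
    g <- asg$genomes[[i]]
    expected <- if (sum(uniq[g]) > 0) asg$aligned_bases[i] else 0
    expect_equal(unname(per_read[asg$read_id[i]]), expected)
  }
  expect_true(all(shares$shared_bases >= 0))
  # brute-force weight check on a sample of reads
  for (i in sample(n, 20)) {
    g <- asg$genomes[[i]]
    rows <- shares[shares$read_id == asg$read_id[i], ]
    w <- uniq[g] / sum(uniq[g])
    if (sum(uniq[g]) > 0) {
      expect_equal(rows$shared_bases[match(g, rows$genome_id)],
                   unname(w) * asg$aligned_bases[i])
    }
  }
})

test_that("the presence rule removes genomes without unique evidence", {
  ev <- tibble::tibble(
    genome_id = c("G1", "G2"),
    unique_reads = c(1L, 0L),
    unique_bases = c(100, 0),
    assigned_bases = c(150, 500)
  )
  kept <- apply_presence_rule(ev)
  expect_identical(kept$genome_id, "G1")
  ev2 <- tibble::tibble(genome_id = c("G1", "G2"),
                        unique_reads = c(5L, 2L),
                        unique_bases = c(500, 200),
                        assigned_bases = c(500, 200))
  expect_identical(apply_presence_rule(ev2, 3)$genome_id, "G1")
  expect_error(apply_presence_rule(ev2, 0),
               class = "sketchtax_invalid_parameter")
})

test_that("evidence assembly accrues unique and shared mass coherently", {
  asg <- make_assignments(
    c("u1", "u2", "u3", "m1"),
    list("G1", "G1", "G2", c("G1", "G2")),
    c(100, 100, 100, 100)
  )
  ev <- genome_evidence(asg)
  # weights 2:1 for the multi-read
  expect_equal(ev$assigned_bases[ev$genome_id == "G1"], 200 + 100 * 2 / 3)
  expect_equal(ev$assigned_bases[ev$genome_id == "G2"], 100 + 100 * 1 / 3)
  expect_true(all(ev$assigned_bases >= ev$unique_bases))
  # mass conservation: total assigned equals unique bases + resolvable multi mass
  expect_equal(sum(ev$assigned_bases), 400)
  # read-count currency
  ev_r <- genome_evidence(asg, currency = "reads")
  expect_equal(sum(ev_r$assigned_bases), 4)
})

test_that("profiles normalize to 100 at each rank and roll up lineages", {
  tax <- fixture_taxonomy()
  ev1 <- tibble::tibble(genome_id = "G1", unique_reads = 2L,
                        unique_bases = 200, assigned_bases = 200)
  p1 <- build_profile(ev1, tax)
  expect_true(all(abs(p1$percentage - 100) < 1e-9))
  expect_setequal(p1$rank, c("superkingdom", "phylum", "class", "order",
                             "family", "genus", "species"))

  ev <- tibble::tibble(genome_id = c("G1", "G3"),
                       unique_reads = c(3L, 1L),
                       unique_bases = c(300, 100),
                       assigned_bases = c(300, 100))
  p <- build_profile(ev, tax)
  genus <- p[p$rank == "genus", ]
  expect_equal(sort(genus$percentage), c(25, 75))
  sums <- tapply(p$percentage, p$rank, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  # genome without a lineage errors by name
  expect_error(build_profile(tibble::tibble(genome_id = "GX", unique_reads = 1L,
                                            unique_bases = 1, assigned_bases = 1),
                             tax),
               "GX", class = "sketchtax_invalid_parameter")
})

test_that("rank roll-up equals a brute-force group-by over lineages", {
  comm <- generate_community(community_spec(n_species = 6, genome_length = 400,
                                            coverage = 1, seed = 9))
  ev <- tibble::tibble(genome_id = comm$genome_ids,
                       unique_reads = 1L,
                       unique_bases = seq(100, 600, 100),
                       assigned_bases = seq(100, 600, 100))
  p <- build_profile(ev, comm$taxonomy)
  frac <- ev$assigned_bases / sum(ev$assigned_bases) * 100
  lins <- split(comm$taxonomy, comm$taxonomy$genome_id)
  for (rank in unique(p$rank)) {
    expected <- list()
    for (i in seq_along(comm$genome_ids)) {
      tx <- ancestor_at_rank(lins[[comm$genome_ids[i]]], rank)
      expected[[tx]] <- (expected[[tx]] %||% 0) + frac[i]
    }
    got <- p[p$rank == rank, ]
    expect_setequal(got$taxid, names(expected))
    for (tx in names(expected)) {
      expect_equal(got$percentage[got$taxid == tx], expected[[tx]])
    }
  }
})

test_that("interior lineage gaps keep rank sums at 100 via taxpath bridging", {
  tax <- tibble::tribble(
    ~genome_id, ~taxid, ~name, ~rank, ~depth,
    "G1", "2", "Bacteria", "superkingdom", 1L,
    "G1", "5001", "GenusA", "genus", 6L,
    "G2", "2", "Bacteria", "superkingdom", 1L,
    "G2", "1002", "PhylumB", "phylum", 2L,
    "G2", "5002", "GenusB", "genus", 6L
  )
  ev <- tibble::tibble(genome_id = c("G1", "G2"), unique_reads = 1L,
                       unique_bases = c(60, 40), assigned_bases = c(60, 40))
  p <- build_profile(ev, tax)
  sums <- tapply(p$percentage, p$rank, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  phylum <- p[p$rank == "phylum", ]
  # G1 has no phylum: its mass sits on a gap-bridged path under Bacteria
  expect_equal(sort(phylum$percentage), c(40, 60))
  expect_true("2|" %in% phylum$taxpath)
})

test_that("the profile is invariant to alignment input order", {
  set.seed(62)
  tax <- fixture_taxonomy()
  n <- 400
  recs <- tibble::tibble(
    read_id = sprintf("r%03d", sample(120, n, TRUE)),
    genome_id = sample(c("G1", "G2", "G3"), n, TRUE),
    read_length = 100,
    aligned_bases = sample(93:100, n, TRUE)
  )
  recs$frac_aligned <- recs$aligned_bases / recs$read_length
  p1 <- profile_alignments(recs, tax)$profile
  p2 <- profile_alignments(recs[sample(n), ], tax)$profile
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("the abundance cutoff drops entries strictly below the threshold", {
  prof <- new_cami_profile(tibble::tibble(
    rank = c("species", "species"), taxid = c("A", "B"),
    taxpath = c("A", "B"), taxpathsn = c("a", "b"),
    percentage = c(99.995, 0.005)
  ))
  cut <- apply_abundance_cutoff(prof, 0.01)
  expect_identical(cut$taxid, "A")
  expect_equal(cut$percentage, 99.995)  # not renormalized by default
  renorm <- apply_abundance_cutoff(prof, 0.01, renormalize = TRUE)
  expect_equal(renorm$percentage, 100)
  expect_equal(nrow(apply_abundance_cutoff(prof, 0)), 2)
  # surviving sets are nested across a cutoff sweep
  set.seed(63)
  pcts <- runif(20); pcts <- pcts / sum(pcts) * 100
  prof2 <- new_cami_profile(tibble::tibble(
    rank = "species", taxid = sprintf("t%02d", 1:20),
    taxpath = sprintf("t%02d", 1:20), taxpathsn = "x", percentage = pcts
  ))
  prev <- prof2$taxid
  for (cutoff in c(0.5, 1, 2, 5, 10)) {
    cur <- apply_abundance_cutoff(prof2, cutoff)$taxid
    expect_true(all(cur %in% prev))
    expect_setequal(cur, prof2$taxid[prof2$percentage >= cutoff])
    prev <- cur
  }
})
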