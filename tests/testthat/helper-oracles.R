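# Independent straight-line oracles and tiny fixture builders. These are
# deliberately naive re-derivations (window loops, dictionary passes) so they
# share no code path with the package implementation they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# brute-force canonical k-mer enumeration over every window
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    w <- toupper(substr(seq, i, i + k - 1))
    if (grepl("[^ACGT]", w)) next
    rc <- revcomp_str(w)
    out <- c(out, if (w <= rc) w else rc)
  }
  sort(unique(out))
}

# second CIGAR parser written character-by-character from the format
# definition: query-consumed ops are M I S = X (H counts toward read length)
oracle_cigar_stats <- function(cigar) {
  chars <- strsplit(cigar, "")[[1]]
  num <- ""
  aligned <- 0
  readlen <- 0
  for (ch in chars) {
    if (ch %in% as.character(0:9)) {
      num <- paste0(num, ch)
    } else {
      len <- as.numeric(num)
      num <- ""
      if (ch %in% c("M", "=", "X")) aligned <- aligned + len
      if (ch %in% c("M", "I", "S", "=", "X", "H")) readlen <- readlen + len
    }
  }
  c(aligned = aligned, read_length = readlen)
}

# straight-line evaluation metrics from first principles
oracle_metrics <- function(truth_tax, truth_pct, pred_tax, pred_pct) {
  tp <- sum(pred_tax %in% truth_tax)
  fp <- sum(!pred_tax %in% truth_tax)
  fn <- sum(!truth_tax %in% pred_tax)
  p <- if (tp + fp > 0) tp / (tp + fp) else 1
  r <- if (tp + fn > 0) tp / (tp + fn) else 1
  all_t <- union(truth_tax, pred_tax)
  l1 <- 0
  for (tx in all_t) {
    tv <- if (tx %in% truth_tax) truth_pct[match(tx, truth_tax)] / 100 else 0
    pv <- if (tx %in% pred_tax) pred_pct[match(tx, pred_tax)] / 100 else 0
    l1 <- l1 + abs(tv - pv)
  }
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
       jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1,
       l1 = l1)
}

# fixture taxonomy: three genomes, two sharing a genus
fixture_taxonomy <- function() {
  tibble::tribble(
    ~genome_id, ~taxid, ~name, ~rank, ~depth,
    "G1", "2", "Bacteria", "superkingdom", 1L,
    "G1", "1001", "PhylumA", "phylum", 2L,
    "G1", "5001", "GenusA", "genus", 6L,
    "G1", "7001", "SpeciesA", "species", 7L,
    "G2", "2", "Bacteria", "superkingdom", 1L,
    "G2", "1001", "PhylumA", "phylum", 2L,
    "G2", "5001", "GenusA", "genus", 6L,
    "G2", "7002", "SpeciesB", "species", 7L,
    "G3", "2", "Bacteria", "superkingdom", 1L,
    "G3", "1002", "PhylumB", "phylum", 2L,
    "G3", "5002", "GenusB", "genus", 6L,
    "G3", "7003", "SpeciesC", "species", 7L
  )
}

# assignment tibble in the shape produced by group_by_read()
make_assignments <- function(read_id, genomes, aligned_bases) {
  tibble::tibble(
    read_id = read_id,
    genomes = lapply(genomes, function(g) sort(unique(g))),
    n_genomes = vapply(genomes, function(g) length(unique(g)), 0L),
    aligned_bases = aligned_bases,
    is_unique = vapply(genomes, function(g) length(unique(g)) == 1L, TRUE)
  )
}

# reads tiling a sequence end to end with the given step
tiling_reads <- function(seq, width, step = 1L) {
  starts <- unique(c(seq(1L, nchar(seq) - width + 1L, by = step),
                     nchar(seq) - width + 1L))
  substring(seq, starts, starts + width - 1L)
}

write_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("r%04d", seq_along(reads))
  writeLines(as.vector(rbind(paste0("@", ids), unname(reads), "+",
                             strrep("I", nchar(reads)))), path)
  path
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}
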