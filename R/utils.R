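# shared argument checks and sequence I/O helpers

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    abort("`k` must be a single positive integer.", class = "sketchtax_invalid_parameter")
  }
  if (k > 32) {
    abort("`k` must be <= 32 for hashing (2-bit packed k-mers).",
          class = "sketchtax_invalid_parameter")
  }
  as.integer(k)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%s, %s%s.",
                  name, if (lower_open) "(" else "[", format(lower),
                  format(upper), if (upper_open) ")" else "]"),
          class = "sketchtax_invalid_parameter")
  }
  x
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "sketchtax_invalid_parameter")
  }
  as.integer(x)
}

# Read FASTA/FASTQ (plain or gzipped) into a plain character vector of
# sequences named by record id. Format sniffed from the first non-empty line.
read_seq_file <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("cannot read sequence file '%s'.", path),
          class = "sketchtax_io_error")
  }
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0) {
    abort(sprintf("sequence file '%s' is empty.", path),
          class = "sketchtax_io_error")
  }
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
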