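#' Build a bottom-k MinHash sketch of a genome
#'
#' Pools the canonical k-mers of all sequences of one genome (records of a
#' draft assembly; windows never span record boundaries), hashes them with the
#' seeded 53-bit hash, and keeps the `sketch_size` smallest distinct hash
#' values. The sketch is over hash values, so distinct k-mers that collide are
#' stored once, matching the bottom-k convention.
#'
#' @param genome_sequences Character vector of DNA strings (one per FASTA
#'   record), or a single path to a (multi-)FASTA file.
#' @param genome_id Identifier for the genome.
#' @param k K-mer length (default 21).
#' @param sketch_size Requested sketch size s (default 1000).
#' @param hash_seed Integer hash seed (default 42); sketches and sample
#'   membership must share one seed.
#' @return A `kmer_sketch` object with fields `genome_id`, `k`, `sketch_size`,
#'   `hashes` (sorted, strictly increasing), `n_distinct_kmers`, `hash_seed`.
#' @export
#' @examples
#' sk <- build_sketch("ACGTACGTAGCTTAGC", "toy", k = 5, sketch_size = 4)
#' sk$hashes
build_sketch <- function(genome_sequences, genome_id, k = 21L,
                         sketch_size = 1000L, hash_seed = 42L) {
  k <- check_k(k)
  sketch_size <- check_count(sketch_size, "sketch_size")
  if (length(genome_sequences) == 1 && !is.na(genome_sequences) &&
      file.exists(genome_sequences)) {
    genome_sequences <- read_seq_file(genome_sequences)
  }
  all_hashes <- kmer_hash_set(genome_sequences, k, hash_seed)
  n_distinct <- length(all_hashes)
  structure(
    list(
      genome_id = as.character(genome_id),
      k = k,
      sketch_size = sketch_size,
      hashes = all_hashes[seq_len(min(sketch_size, n_distinct))],
      n_distinct_kmers = n_distinct,
      hash_seed = as.integer(hash_seed)
    ),
    class = "kmer_sketch"
  )
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf(
    "<kmer_sketch> %s: k=%d, s=%d, |sketch|=%d of %d distinct k-mers (seed %d)\n",
    x$genome_id, x$k, x$sketch_size, length(x$hashes),
    x$n_distinct_kmers, x$hash_seed
  ))
  invisible(x)
}

#' Sketch a collection of genome FASTA files
#'
#' @param genome_paths Named character vector of FASTA paths; names are the
#'   genome ids (file stems used when unnamed).
#' @inheritParams build_sketch
#' @return A named list of [build_sketch()] objects.
#' @export
build_sketches <- function(genome_paths, k = 21L, sketch_size = 1000L,
                           hash_seed = 42L) {
  ids <- names(genome_paths)
  if (is.null(ids)) {
    ids <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(genome_paths))
  }
  sketches <- purrr::map2(
    genome_paths, ids,
    function(p, id) build_sketch(read_seq_file(p), id, k, sketch_size, hash_seed)
  )
  rlang::set_names(sketches, ids)
}

SKETCH_DB_FORMAT <- "sketchtax-sketch-db-v1"

#' Serialize a sketch database to a directory
#'
#' Writes one plain-text hash file per genome plus a tab-separated index
#' (`genome_id`, `path`, `k`, `sketch_size`, `hash_seed`, `n_distinct_kmers`)
#' with a format-version header. The representation round-trips exactly:
#' hash values are 53-bit integers printed in full.
#'
#' @param sketches Named list of `kmer_sketch` objects.
#' @param dir Output directory (created if missing).
#' @return The index path, invisibly.
#' @export
write_sketch_db <- function(sketches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- sprintf("%s.sketch.txt", vapply(sketches, `[[`, "", "genome_id"))
  for (i in seq_along(sketches)) {
    writeLines(format(sketches[[i]]$hashes, scientific = FALSE, trim = TRUE),
               file.path(dir, rel[i]))
  }
  index <- tibble(
    genome_id = vapply(sketches, `[[`, "", "genome_id"),
    path = rel,
    k = vapply(sketches, `[[`, 0L, "k"),
    sketch_size = vapply(sketches, `[[`, 0L, "sketch_size"),
    hash_seed = vapply(sketches, `[[`, 0L, "hash_seed"),
    n_distinct_kmers = vapply(sketches, `[[`, 0L, "n_distinct_kmers")
  )
  index_path <- file.path(dir, "sketches.tsv")
  writeLines(paste0("# ", SKETCH_DB_FORMAT), index_path)
  readr::write_tsv(index, index_path, append = TRUE, col_names = TRUE)
  invisible(index_path)
}

#' Load a sketch database written by [write_sketch_db()]
#'
#' @param dir Directory containing `sketches.tsv` and the per-genome files.
#' @return A named list of `kmer_sketch` objects.
#' @export
read_sketch_db <- function(dir) {
  index_path <- file.path(dir, "sketches.tsv")
  if (!file.exists(index_path)) {
    abort(sprintf("no sketch index at '%s'.", index_path),
          class = "sketchtax_io_error")
  }
  header <- readLines(index_path, n = 1L)
  if (!identical(header, paste0("# ", SKETCH_DB_FORMAT))) {
    abort(sprintf("unrecognized sketch database format: '%s'.", header),
          class = "sketchtax_io_error")
  }
  index <- readr::read_tsv(index_path, comment = "#", show_col_types = FALSE)
  sketches <- purrr::pmap(index, function(genome_id, path, k, sketch_size,
                                          hash_seed, n_distinct_kmers) {
    hashes <- as.numeric(readLines(file.path(dir, path)))
    structure(
      list(genome_id = genome_id, k = as.integer(k),
           sketch_size = as.integer(sketch_size), hashes = hashes,
           n_distinct_kmers = as.integer(n_distinct_kmers),
           hash_seed = as.integer(hash_seed)),
      class = "kmer_sketch"
    )
  })
  rlang::set_names(sketches, index$genome_id)
}
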