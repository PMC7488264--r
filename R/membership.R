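#' Build a queryable membership structure over a sample's k-mers
#'
#' Enumerates the canonical k-mers of every read in the supplied FASTA/FASTQ
#' files (plain or gzipped; interleaved pairs are treated as independent
#' reads) and stores their hash values either exactly (a sorted set, the
#' default) or in a Bloom filter sized for a requested false-positive rate.
#' Both backends have no false negatives; the Bloom backend trades memory for
#' a known false-positive rate `p` that the containment estimator corrects
#' for.
#'
#' @param read_files Character vector of FASTA/FASTQ paths.
#' @param k K-mer length; must match the sketches it will be queried with.
#' @param backend `"exact_set"` (default) or `"bloom"`.
#' @param bloom_fp_rate Target Bloom false-positive probability in (0, 1);
#'   ignored for the exact backend.
#' @param hash_seed Integer hash seed; must match the sketch seed.
#' @return A `sample_membership` object.
#' @export
build_sample_membership <- function(read_files, k = 21L,
                                    backend = c("exact_set", "bloom"),
                                    bloom_fp_rate = 0.01, hash_seed = 42L) {
  k <- check_k(k)
  backend <- match.arg(backend)
  if (backend == "bloom") {
    check_scalar_number(bloom_fp_rate, "bloom_fp_rate", 0, 1,
                        lower_open = TRUE, upper_open = TRUE)
  }
  seqs <- unlist(lapply(read_files, read_seq_file), use.names = FALSE)
  hashes <- kmer_hash_set(seqs, k, hash_seed)
  membership_from_hashes(hashes, k, backend, bloom_fp_rate, hash_seed)
}

# Construct a membership from pre-computed distinct hash values (also used by
# tests to build exactly controlled samples).
membership_from_hashes <- function(hashes, k, backend = "exact_set",
                                   bloom_fp_rate = 0.01, hash_seed = 42L) {
  n <- length(hashes)
  obj <- list(
    k = as.integer(k),
    backend = backend,
    bloom_fp_rate = if (backend == "bloom") bloom_fp_rate else 0,
    n_kmers_inserted = n,
    hash_seed = as.integer(hash_seed)
  )
  if (backend == "exact_set") {
    obj$hashes <- sort(hashes)
  } else {
    # classic sizing: m = -n ln p / (ln 2)^2 bits, nh = m/n ln 2 probes
    n_eff <- max(n, 1L)
    m_bits <- max(64, ceiling(-n_eff * log(bloom_fp_rate) / log(2)^2))
    nh <- max(1L, as.integer(round(m_bits / n_eff * log(2))))
    obj$m_bits <- m_bits
    obj$n_hash_funs <- nh
    obj$bits <- cpp_bloom_build(hashes, m_bits, nh)
  }
  structure(obj, class = "sample_membership")
}

#' @export
print.sample_membership <- function(x, ...) {
  extra <- if (x$backend == "bloom") {
    sprintf(", fp_rate=%g, m=%d bits", x$bloom_fp_rate, as.integer(x$m_bits))
  } else ""
  cat(sprintf("<sample_membership> k=%d, backend=%s, %d k-mers inserted%s (seed %d)\n",
              x$k, x$backend, x$n_kmers_inserted, extra, x$hash_seed))
  invisible(x)
}

#' Query a sample membership with k-mer hash values
#'
#' @param membership A [build_sample_membership()] object.
#' @param hashes Numeric vector of canonical k-mer hash values (same `k` and
#'   seed as the membership).
#' @return Logical vector; `TRUE` where the hash tests present. Exact backend
#'   has zero false positives; Bloom backend has rate ~`bloom_fp_rate`.
#' @export
query_membership <- function(membership, hashes) {
  stopifnot(inherits(membership, "sample_membership"))
  if (membership$backend == "exact_set") {
    if (length(membership$hashes) == 0) return(rep(FALSE, length(hashes)))
    idx <- findInterval(hashes, membership$hashes)
    idx > 0 & membership$hashes[pmax(idx, 1)] == hashes
  } else {
    cpp_bloom_query(membership$bits, membership$m_bits,
                    membership$n_hash_funs, hashes)
  }
}

#' Query membership of k-mer strings
#'
#' Convenience wrapper canonicalizing and hashing `kmers` before querying;
#' errors if the k-mer length does not match the membership's `k`.
#'
#' @inheritParams query_membership
#' @param kmers Character vector of k-mers.
#' @return Logical vector.
#' @export
query_kmers <- function(membership, kmers) {
  bad <- nchar(kmers) != membership$k
  if (any(bad)) {
    abort(sprintf("k-mer length %d does not match membership k = %d.",
                  nchar(kmers[bad][1]), membership$k),
          class = "sketchtax_invalid_parameter")
  }
  h <- hash_kmers(kmers, membership$k, membership$hash_seed)
  out <- rep(FALSE, length(kmers))
  out[!is.na(h)] <- query_membership(membership, h[!is.na(h)])
  out
}
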