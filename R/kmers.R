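#' Enumerate the canonical k-mers of a DNA sequence
#'
#' A canonical k-mer is the lexicographic minimum of a k-mer and its reverse
#' complement, which makes k-mer sets strand-independent. Windows containing
#' any character outside `A/C/G/T` (case-insensitive) are skipped rather than
#' expanded, and sequences shorter than `k` yield an empty set.
#'
#' @param sequence A single DNA string.
#' @param k K-mer length in bases (1--32).
#' @return A character vector of distinct canonical k-mers (unordered set
#'   semantics; returned sorted).
#' @export
#' @examples
#' canonical_kmers("ACGT", 2)   # "GT" canonicalizes to "AC"
#' canonical_kmers("AANA", 2)   # windows containing N are skipped
canonical_kmers <- function(sequence, k) {
  k <- check_k(k)
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    abort("`sequence` must be a single DNA string.",
          class = "sketchtax_invalid_parameter")
  }
  cpp_canonical_kmers(sequence, k)
}

#' Hash canonical k-mers
#'
#' Applies the package's seeded hash to each supplied k-mer (canonicalizing
#' first, so a k-mer and its reverse complement hash identically). Hash values
#' are 53-bit unsigned integers stored exactly in doubles; all sketches and
#' membership structures that are compared must share one seed.
#'
#' @param kmers Character vector of k-mers, all of length `k`.
#' @param k K-mer length (1--32).
#' @param hash_seed Integer hash seed (default 42).
#' @return Numeric vector of hash values; `NA` for k-mers containing non-ACGT
#'   characters or of the wrong length.
#' @export
hash_kmers <- function(kmers, k, hash_seed = 42L) {
  k <- check_k(k)
  cpp_hash_kmers(as.character(kmers), k, as.numeric(hash_seed))
}

# All distinct canonical k-mer hashes pooled over a character vector of
# sequences (the exact reference set behind sketches and memberships).
kmer_hash_set <- function(sequences, k, hash_seed = 42L) {
  k <- check_k(k)
  cpp_kmer_hash_set(as.character(sequences), k, as.numeric(hash_seed))
}
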