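# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic community
#'
#' Describes a mock metagenome: `n_species` species genomes of i.i.d. uniform
#' DNA, optionally several strains per species (copies with i.i.d.
#' substitutions at `strain_divergence`), relative abundances over all
#' genomes (zeros mark absent organisms), and a simple substitution-only read
#' error model. The generator emulates the inputs a profiler sees — distinct
#' reference genomes, error-bearing reads, a taxonomy — not the phylogenetic
#' structure, repeat content or indel errors of real communities.
#'
#' @param n_species Number of species (default 10).
#' @param strains_per_species Strains per species (default 1).
#' @param genome_length Genome length in bases (default 1e5).
#' @param strain_divergence Per-base substitution rate between a strain and
#'   its parent genome (default 0.001, in the range of same-species strain
#'   divergence).
#' @param abundances Relative abundances over all `n_species *
#'   strains_per_species` genomes, summing to 1 (zeros allowed); default
#'   `1/i` weights, normalized.
#' @param read_length Read length in bases (default 100).
#' @param coverage Expected fold-coverage of the abundance-weighted community
#'   pool (default 20): genome g receives `round(coverage * genome_length *
#'   abundance_g / read_length)` reads.
#' @param error_rate Per-base read substitution probability (default 0.01).
#' @param seed RNG seed (default 1).
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_species = 10L, strains_per_species = 1L,
                           genome_length = 1e5, strain_divergence = 0.001,
                           abundances = NULL, read_length = 100L,
                           coverage = 20, error_rate = 0.01, seed = 1L) {
  n_species <- check_count(n_species, "n_species")
  strains_per_species <- check_count(strains_per_species, "strains_per_species")
  genome_length <- check_count(genome_length, "genome_length")
  read_length <- check_count(read_length, "read_length")
  check_scalar_number(strain_divergence, "strain_divergence", 0, 1, upper_open = TRUE)
  check_scalar_number(error_rate, "error_rate", 0, 1, upper_open = TRUE)
  check_scalar_number(coverage, "coverage", 0, Inf, lower_open = TRUE)
  n_genomes <- n_species * strains_per_species
  if (is.null(abundances)) {
    abundances <- (1 / seq_len(n_genomes)) / sum(1 / seq_len(n_genomes))
  }
  if (length(abundances) != n_genomes) {
    abort(sprintf("`abundances` must have length %d (one per genome).", n_genomes),
          class = "sketchtax_invalid_parameter")
  }
  if (abs(sum(abundances) - 1) > 1e-9 || any(abundances < 0)) {
    abort("`abundances` must be non-negative and sum to 1.",
          class = "sketchtax_invalid_parameter")
  }
  structure(
    list(n_species = n_species, strains_per_species = strains_per_species,
         genome_length = genome_length, strain_divergence = strain_divergence,
         abundances = abundances, read_length = read_length,
         coverage = coverage, error_rate = error_rate, seed = as.integer(seed)),
    class = "community_spec"
  )
}

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# synthetic but structured lineage: two species per genus, two genera per
# family, and so on up the hierarchy; taxids are synthetic numeric strings
species_lineage <- function(i) {
  g <- ceiling(i / 2); f <- ceiling(g / 2); o <- ceiling(f / 2)
  cl <- ceiling(o / 2); p <- ceiling(cl / 2)
  tibble(
    taxid = c("2", sprintf("1%04d", p), sprintf("2%04d", cl),
              sprintf("3%04d", o), sprintf("4%04d", f), sprintf("5%04d", g),
              sprintf("7%04d", i)),
    name = c("Bacteria", sprintf("Phylum%d", p), sprintf("Class%d", cl),
             sprintf("Order%d", o), sprintf("Family%d", f),
             sprintf("Genus%d", g), sprintf("Species%d", i)),
    rank = c("superkingdom", "phylum", "class", "order", "family", "genus",
             "species"),
    depth = 1:7
  )
}

#' Generate a synthetic community
#'
#' Writes one FASTA per genome, a taxonomy TSV, and the ground-truth CAMI
#' profile implied by the spec's abundances (normalized at every rank).
#' Byte-identical across runs with the same spec.
#'
#' @param spec A [community_spec()].
#' @param dir Output directory (created).
#' @return A list: `spec`, `genome_ids`, `genomes` (named character vector of
#'   sequences), `genome_paths`, `taxonomy` (tidy tibble), `taxonomy_path`,
#'   `truth` (`cami_profile` over present genomes), `truth_path`,
#'   `abundances` (named).
#' @export
generate_community <- function(spec, dir = tempfile("community")) {
  stopifnot(inherits(spec, "community_spec"))
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  n_str <- spec$strains_per_species
  out <- with_seed(spec$seed, {
    genomes <- character(0)
    tax_rows <- list()
    for (i in seq_len(spec$n_species)) {
      parent <- random_genome(spec$genome_length)
      for (j in seq_len(n_str)) {
        gid <- if (n_str == 1) sprintf("sp%02d", i) else sprintf("sp%02d_st%d", i, j)
        seq <- if (j == 1) parent else {
          cpp_add_substitutions(parent, spec$strain_divergence)
        }
        genomes[gid] <- seq
        lin <- species_lineage(i)
        if (n_str > 1) {
          lin <- dplyr::bind_rows(lin, tibble(
            taxid = sprintf("8%02d%02d", i, j), name = sprintf("%s strain %d", lin$name[7], j),
            rank = "strain", depth = 8L
          ))
        }
        tax_rows[[gid]] <- dplyr::mutate(lin, genome_id = gid, .before = 1)
      }
    }
    list(genomes = genomes, taxonomy = purrr::list_rbind(tax_rows))
  })
  genomes <- out$genomes
  taxonomy <- out$taxonomy
  genome_paths <- file.path(dir, "genomes", paste0(names(genomes), ".fasta"))
  names(genome_paths) <- names(genomes)
  for (g in names(genomes)) {
    set <- Biostrings::DNAStringSet(rlang::set_names(genomes[[g]], g))
    Biostrings::writeXStringSet(set, genome_paths[[g]])
  }
  taxonomy_path <- file.path(dir, "taxonomy.tsv")
  write_taxonomy(taxonomy, taxonomy_path)
  abundances <- rlang::set_names(spec$abundances, names(genomes))
  present <- abundances[abundances > 0]
  truth <- build_profile(
    tibble(genome_id = names(present), unique_reads = 1L,
           unique_bases = present, assigned_bases = present),
    taxonomy, sample_id = "truth"
  )
  truth_path <- file.path(dir, "truth.profile")
  write_cami_profile(truth, truth_path)
  list(spec = spec, genome_ids = names(genomes), genomes = genomes,
       genome_paths = genome_paths, taxonomy = taxonomy,
       taxonomy_path = taxonomy_path, truth = truth, truth_path = truth_path,
       abundances = abundances)
}

#' Sample error-bearing reads from a community
#'
#' Draws reads with uniform start positions from both strands, in numbers
#' proportional to `abundance * genome_length / read_length` at the spec's
#' coverage, applies i.i.d. substitution errors, and records the true origin
#' of every read.
#'
#' @param community Result of [generate_community()].
#' @param out_fastq Output FASTQ path (default inside a tempdir).
#' @return A list: `fastq`, `origins` (tibble `read_id`, `genome_id`,
#'   `start`, `strand`), `n_reads`.
#' @export
sample_reads <- function(community, out_fastq = tempfile(fileext = ".fastq")) {
  spec <- community$spec
  if (spec$read_length > spec$genome_length) {
    abort("`read_length` exceeds `genome_length`.",
          class = "sketchtax_invalid_parameter")
  }
  rl <- spec$read_length
  res <- with_seed(spec$seed + 1L, {
    per_genome <- purrr::map(names(community$genomes), function(g) {
      ab <- community$abundances[[g]]
      n <- round(spec$coverage * nchar(community$genomes[[g]]) * ab / rl)
      if (n == 0) return(NULL)
      starts <- sample.int(nchar(community$genomes[[g]]) - rl + 1L, n,
                           replace = TRUE)
      tibble(genome_id = g, start = starts)
    })
    origins <- purrr::list_rbind(purrr::compact(per_genome))
    if (nrow(origins) == 0) {
      list(origins = origins, reads = character(0))
    } else {
      origins$strand <- sample(c("+", "-"), nrow(origins), replace = TRUE)
      origins$read_id <- sprintf("r%06d", seq_len(nrow(origins)))
      reads <- substring(community$genomes[origins$genome_id], origins$start,
                         origins$start + rl - 1L)
      rev <- origins$strand == "-"
      if (any(rev)) reads[rev] <- revcomp(reads[rev])
      if (spec$error_rate > 0) {
        reads <- cpp_add_substitutions(reads, spec$error_rate)
      }
      list(origins = origins[, c("read_id", "genome_id", "start", "strand")],
           reads = rlang::set_names(reads, origins$read_id))
    }
  })
  lines <- if (length(res$reads) > 0) {
    rbind(paste0("@", names(res$reads)), res$reads, "+",
          strrep("I", nchar(res$reads)))
  } else {
    matrix(character(0), nrow = 0)
  }
  writeLines(as.vector(lines), out_fastq)
  list(fastq = out_fastq, origins = res$origins, n_reads = length(res$reads))
}
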