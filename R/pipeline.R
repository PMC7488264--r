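#' Run the full profiling pipeline
#'
#' Orchestrates sketching, containment pre-filtering, alignment against the
#' subset database, and profile generation: build (or load) genome sketches,
#' build the sample k-mer membership, estimate per-genome containment, select
#' the subset database at the containment cutoff (one strain per species by
#' default), align the reads with the built-in toy aligner or minimap2,
#' filter alignments at the aligned-fraction threshold, and emit a CAMI
#' profile. All intermediate artifacts (containment report, subset FASTA and
#' sidecar, SAM, profile) plus a JSON manifest with the effective
#' configuration and input checksums are written under `out_dir`.
#'
#' @param read_files FASTQ/FASTA path(s) of the sample reads.
#' @param genome_paths Named character vector: genome_id -> reference FASTA.
#' @param taxonomy Tidy taxonomy tibble from [load_taxonomy()], or a path to
#'   the taxonomy TSV.
#' @param out_dir Output directory.
#' @param k,sketch_size,hash_seed Sketching parameters (defaults 21, 1000,
#'   42).
#' @param sketches Optional pre-built sketch list or [write_sketch_db()]
#'   directory; built from `genome_paths` when `NULL`.
#' @param membership_backend,bloom_fp_rate Sample membership options.
#' @param cutoff Containment cutoff for the subset database (default 0.01).
#' @param strain_mode `"best_per_species"` (default) or `"all_strains"`.
#' @param aligner `"toy"` (default; built-in, no external dependency) or
#'   `"minimap2"` (requires the executable on the PATH).
#' @param toy_k_seed Seed length for the toy aligner (default 16).
#' @param min_frac Aligned-fraction threshold (default 0.95).
#' @param min_unique_reads Presence threshold (default 1).
#' @param min_abundance Post-hoc abundance cutoff in percent (default 0).
#' @param currency `"bases"` (default) or `"reads"`.
#' @param sample_id Sample identifier (default `"sample"`).
#' @return A list: `profile`, `evidence`, `containment`, `subset`, `paths`
#'   (named list of written files).
#' @export
run_end_to_end <- function(read_files, genome_paths, taxonomy,
                           out_dir = tempfile("sketchtax_run"),
                           k = 21L, sketch_size = 1000L, hash_seed = 42L,
                           sketches = NULL,
                           membership_backend = "exact_set",
                           bloom_fp_rate = 0.01,
                           cutoff = 0.01,
                           strain_mode = "best_per_species",
                           aligner = c("toy", "minimap2"),
                           toy_k_seed = 16L,
                           min_frac = 0.95, min_unique_reads = 1L,
                           min_abundance = 0, currency = "bases",
                           sample_id = "sample") {
  aligner <- match.arg(aligner)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(taxonomy)) taxonomy <- load_taxonomy(taxonomy)
  paths <- list(
    containment = file.path(out_dir, "containment.tsv"),
    subset_fasta = file.path(out_dir, "subset.fasta"),
    subset_sidecar = file.path(out_dir, "subset.tsv"),
    alignments = file.path(out_dir, "alignments.sam"),
    profile = file.path(out_dir, "profile.cami"),
    manifest = file.path(out_dir, "manifest.json")
  )

  empty_reads <- all(vapply(read_files, function(f) {
    !file.exists(f) || file.info(f)$size == 0
  }, TRUE))
  if (empty_reads) {
    warn("no reads in input: writing a header-only profile.")
    profile <- new_cami_profile(
      tibble(rank = character(), taxid = character(), taxpath = character(),
             taxpathsn = character(), percentage = numeric()),
      sample_id = sample_id
    )
    write_cami_profile(profile, paths$profile)
    return(list(profile = profile, evidence = tibble(),
                containment = tibble(), subset = tibble(), paths = paths))
  }

  if (is.null(sketches)) {
    sketches <- build_sketches(genome_paths, k, sketch_size, hash_seed)
  } else if (is.character(sketches)) {
    sketches <- read_sketch_db(sketches)
  }
  membership <- build_sample_membership(read_files, k = k,
                                        backend = membership_backend,
                                        bloom_fp_rate = bloom_fp_rate,
                                        hash_seed = hash_seed)
  containment <- containment_table(sketches, membership, taxonomy)
  subset <- select_subset(containment, cutoff = cutoff,
                          strain_mode = strain_mode)
  readr::write_tsv(
    dplyr::mutate(containment,
                  selected = .data$genome_id %in% subset$genome_id),
    paths$containment
  )
  sub_files <- write_subset_fasta(subset, genome_paths, paths$subset_fasta,
                                  paths$subset_sidecar)

  if (nrow(subset) == 0) {
    warn("no genome passed the containment cutoff: profile is empty.")
    records <- tibble(read_id = character(), genome_id = character(),
                      read_length = numeric(), aligned_bases = numeric(),
                      frac_aligned = numeric())
    writeLines("@HD\tVN:1.6\tSO:unknown", paths$alignments)
  } else if (aligner == "toy") {
    toy_align(read_files[[1]], paths$subset_fasta, k_seed = toy_k_seed,
              out_sam = paths$alignments)
    records <- parse_alignments(paths$alignments, sub_files$map, "sam")
  } else {
    status <- system2("minimap2",
                      c("-a", "--secondary=yes", "-N", "50",
                        shQuote(paths$subset_fasta),
                        vapply(read_files, shQuote, "")),
                      stdout = paths$alignments, stderr = FALSE)
    if (!identical(status, 0L)) {
      abort("minimap2 alignment failed.", class = "sketchtax_stage_error")
    }
    records <- parse_alignments(paths$alignments, sub_files$map, "sam")
  }

  res <- profile_alignments(records, taxonomy, min_frac = min_frac,
                            min_unique_reads = min_unique_reads,
                            min_abundance = min_abundance,
                            currency = currency, sample_id = sample_id)
  write_cami_profile(res$profile, paths$profile)

  manifest <- list(
    package = "sketchtax",
    version = as.character(utils::packageVersion("sketchtax")),
    config = list(k = k, sketch_size = sketch_size, hash_seed = hash_seed,
                  cutoff = cutoff, strain_mode = strain_mode,
                  aligner = aligner, min_frac = min_frac,
                  min_unique_reads = min_unique_reads,
                  min_abundance = min_abundance, currency = currency,
                  sample_id = sample_id),
    inputs = list(
      reads = unname(vapply(read_files, function(f)
        unname(tools::md5sum(f)), "")),
      genomes = as.list(vapply(genome_paths, function(f)
        unname(tools::md5sum(f)), ""))
    ),
    outputs = lapply(paths[names(paths) != "manifest"], basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  list(profile = res$profile, evidence = res$evidence,
       containment = containment, subset = subset, paths = paths)
}
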