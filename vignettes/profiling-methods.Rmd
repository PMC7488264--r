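---
title: "Containment pre-filtering and alignment-based profiling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Containment pre-filtering and alignment-based profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sketchtax)
library(dplyr)
```

sketchtax estimates the relative abundances of organisms in a shotgun
metagenome in two stages. A *pre-filter* reduces a reference genome
collection to the small subset that could plausibly be in the sample, using
containment min hash sketches; an *alignment stage* then assigns reads to
those candidate genomes, resolves multi-aligned reads, and emits a
rank-by-rank taxonomic profile in the CAMI/bioboxes format. This vignette
documents the model behind each stage, the tunable parameters, and the
design and numerical choices the implementation makes.

## Stage 1: containment min hash pre-filtering

For a reference genome $A$ and a read sample $B$, both viewed as sets of
canonical $k$-mers, the **containment index**

$$C(A, B) = \frac{|A \cap B|}{|A|}$$

is the fraction of the genome's $k$-mers present in the reads. A genome that
is truly in the sample at even modest coverage has $C$ near 1 (sequencing
errors knock out a minority of $k$-mer copies, but most genome positions are
covered by an error-free copy); an unrelated genome has $C$ near 0 because
random $k$-mer collisions at $k = 21$ are vanishingly rare. $C$ is estimated
without touching most of the genome via a **bottom-k MinHash sketch**: hash
every canonical $k$-mer of $A$ with a fixed seeded hash, keep the $s$
smallest distinct values, and count what fraction of those $s$ values are
present in the sample's $k$-mer set. Because a uniform hash makes the sketch
a simple random sample of $A$'s $k$-mers, the hit count is
$\mathrm{Binomial}(s, C)$ (slightly tighter, hypergeometric, when $s$ is a
large fraction of $|A|$), so the standard error is
$\sqrt{C(1-C)/s} \le 0.016$ at the default $s = 1000$.

The sample side is a membership structure over the reads' $k$-mer hashes:
an exact sorted set by default, or a Bloom filter for large samples. A Bloom
filter with false-positive rate $p$ inflates the raw estimate $\hat{C}$, so
the estimator corrects it to $(\hat{C} - p)/(1 - p)$ and clamps to $[0,1]$.
Both backends have no false negatives.

Genomes with $C \ge$ `cutoff` (default **0.01**, inclusive) form the subset
database. The cutoff is deliberately liberal: its job is recall, not
precision — the alignment stage is what removes the remaining false
positives, and genomes that cannot reasonably be present would only
confound alignment if kept. By default only the highest-containment strain
per species survives (`best_per_species`), ties broken by lexicographically
smallest genome id so the result is deterministic; genomes without a
species-level taxid are treated as singleton species and never collapsed.

Parameters:

| parameter | default | meaning |
|---|---|---|
| `k` | 21 bases | $k$-mer length; shared by all sketches and the membership |
| `sketch_size` | 1000 | bottom-k sketch size $s$ per genome |
| `hash_seed` | 42 | seed of the 64-bit hash; recorded in sketch files, mixed-seed queries are rejected |
| `cutoff` | 0.01 | inclusive containment threshold for the subset database |
| `bloom_fp_rate` | 0.01 | target Bloom false-positive probability (Bloom backend only) |

`k` and `sketch_size` are our defaults rather than field-mandated
constants: $k = 21$ is the common MinHash sketching choice — long enough
that cross-genome collisions are negligible, short enough that a 1%
per-base error rate leaves most $k$-mer copies intact — and $s = 1000$
keeps the binomial standard error below 0.016 everywhere. Both are
configurable, and every component checks that it shares one $(k,
\text{seed})$ pair with its partners.

## Stage 2: alignment, the presence rule, and redistribution

Reads are aligned against the subset database (record ids are prefixed with
their genome id so every alignment is attributable). From each SAM line the
package computes the read bases consumed by alignment-match operations
(`M`/`=`/`X`, query-side) and keeps alignments covering at least
`min_frac = 0.95` of the read (inclusive). The 95% rule discards poor
alignments while tolerating a few errors, and it guarantees that a
multi-aligned read's surviving alignments are all of comparable quality.
Secondary and supplementary alignments are retained — multi-alignment is
the point — and a read's alignments are deduplicated at the genome level
before classifying it as *uniquely aligned* (one genome) or
*multi-aligned* (two or more).

Abundance is accumulated in **aligned bases** (a read-count mode is
available via `currency = "reads"`). A read's base mass is the maximum
passing `aligned_bases` over its alignments; since all passing alignments
cover $\ge$ 95% of the read they differ by at most a few bases, and a
single well-defined mass keeps the accounting order-invariant.

Unique reads accrue directly to their genome. Each multi-aligned read is
then split across the genomes it hits, proportionally to their **unique
read counts**: with unique counts $u_g$ over the read's genome set $G$,
genome $g$ receives the fraction $u_g / \sum_{h \in G} u_h$ of the read's
bases. (Unique *reads*, not unique bases, set the weights; mass is still
delivered in bases.) A read whose genomes all lack unique evidence is
discarded rather than split uniformly — splitting it would inject mass into
genomes the presence rule is about to delete, breaking mass accounting.
This is a single-pass scheme; iterative, posterior-reweighted reassignment
is a known refinement and out of scope.

The **presence rule** then removes every genome with fewer than
`min_unique_reads` (default 1) uniquely aligned reads, *including* whatever
multi-read mass it had already received: one high-quality unique alignment
is the standard of evidence for calling an organism present, and discarded
genomes' mass is dropped, not re-redistributed (re-distribution would make
the result depend on deletion order).

Surviving genomes' masses are normalized to relative abundances summing to
100% and rolled up the eight-rank hierarchy (superkingdom … strain): the
abundance of a taxon at rank $r$ is the sum over present genomes whose
lineage passes through it. By default the profile covers ranks down to the
deepest rank any surviving genome has. A genome whose lineage lacks an
interior rank contributes there through its deepest available ancestor,
with an empty field at the gap position of the `TAXPATH` (the CAMI
convention), so every emitted rank still sums to 100 within $10^{-6}$. An
optional `unmapped_fraction` scales all percentages down so rank sums fall
below 100, for samples where a known fraction of the reads has no reference
representative.

Profiles serialize to the CAMI/bioboxes profiling format (`@SampleID`,
`@Version:0.9.1`, fixed eight-rank `@Ranks` header, then
`TAXID/RANK/TAXPATH/TAXPATHSN/PERCENTAGE` rows ordered by rank depth then
descending percentage, six decimal places). The reader is tolerant —
case-insensitive headers, comments, blank lines — but rejects rows whose
rank is undeclared, with the offending line number. `apply_abundance_cutoff()`
removes entries strictly below a percentage threshold at every rank and by
default does *not* renormalize, so reported abundances remain comparable to
their pre-cutoff values (a `renormalize` flag rescales each rank to 100).

## Evaluation metrics

`compare_profiles()` scores a predicted profile against a truth profile at
one rank: presence sets are taxids with positive abundance, the abundance
cutoff is applied to the predicted profile only (matching how profilers are
thresholded in practice), and it reports precision, recall, F1, Jaccard,
and the L1 error $\sum_t |\hat{a}_t - a_t|$ over the **union** of taxa with
abundances as fractions (range 0–2; missing taxa contribute their full
abundance), plus the rescaled score $1 - \mathrm{L1}/2$ so that higher is
better. When both presence sets are empty the set metrics are vacuously 1.
`cutoff_sweep()` recomputes the metrics across a cutoff grid; on
communities whose true taxa all sit well above the largest false-positive
abundance, F1 reaches 1 once the cutoff separates the groups.

## The synthetic community generator

`community_spec()` + `generate_community()` + `sample_reads()` +
`toy_align()` make every stage testable with no external data. Species
genomes are i.i.d. uniform DNA; strains are copies with i.i.d.
substitutions at `strain_divergence` (default 0.001, the order of
within-species strain divergence, and low enough that most 100 bp reads are
compatible with both strains — which is exactly what exercises the
multi-alignment machinery). Reads of length 100 are drawn uniformly from
both strands with i.i.d. substitution errors (default 1%), and every read's
true origin is recorded. `coverage` is defined as the expected
fold-coverage of the abundance-weighted community pool: genome $g$ receives
$\mathrm{round}(\text{coverage} \cdot L_g \cdot a_g / \ell)$ reads, so at
the default 20× a genome at 10% abundance in a five-member community is
covered about 2× — deliberately realistic for low-abundance members, and
still far above what the containment pre-filter or the presence rule needs.

The toy aligner is an ungapped seed-and-verify matcher: exact 16-mer seeds
at the read's start, middle and end (both orientations) against a full
positional index of the subset database, each hit verified by
base-by-base comparison at the implied offset and reported wherever
identity over the read reaches 90%, with `S/M/S` CIGARs. With three seeds
and 1% errors, the probability that every seed of a read carries an error
is about $(1 - 0.99^{16})^3 \approx 0.3\%$, so read loss is negligible and
effectively uniform across genomes.

What the generator does **not** emulate: indels (the substitution-only
model is what keeps the toy CIGARs to `S/M/S`; a production aligner such as
minimap2, which the pipeline can call instead, handles them), quality-score
structure, GC/coverage bias, repeats and shared gene content between
unrelated species, and realistic phylogenetic similarity between community
members. Passing tests therefore demonstrate the correctness of the
sketching, filtering, resolution and accounting machinery — not robustness
to the homology structure of real pan-genomes, where containment between
related species is the hard part of the problem.

## Numerical and design choices

- **Hash.** Canonical $k$-mers ($k \le 32$) are packed 2 bits per base and
  hashed with a seeded splitmix64 finalizer, truncated to the top 53 bits so
  hash values are exactly representable as R doubles. The truncation leaves
  collision probabilities at $\sim 10^{-10}$ for desk-scale genome sets and
  keeps sketch files plain text with exact round-trips.
- **Canonicalization** is the lexicographic minimum of a window and its
  reverse complement; windows containing any non-ACGT character are skipped,
  never expanded, and windows never span FASTA record boundaries.
- **Ties and duplicates.** Sketches are sets of hash *values*: distinct
  $k$-mers colliding under the hash are stored once (bottom-k convention).
  Strain collapsing and profile output use lexicographic genome/taxid
  tie-breaks so all outputs are deterministic and order-invariant.
- **Inclusive thresholds.** The containment cutoff, the 95% aligned-fraction
  rule, the presence rule and the abundance cutoff all use $\ge$, so
  boundary cases are well defined and testable.
- **Degenerate inputs.** An empty genome yields an empty sketch (containment
  0, not an error); an empty subset or an empty reads file yields a warning
  and a header-only profile; an empty truth/prediction pair scores vacuous
  1s.
- **Problem sizes.** The test suite and examples run on communities of ten
  100 kb genomes at 20× pool coverage (about 20,000 reads), where the full
  pipeline completes in a few seconds; these sizes give binomial sampling
  errors far below the tested tolerances while keeping the suite fast.

## Worked example

```{r example}
ab <- c(0.3, 0.25, 0.2, 0.15, 0.1, rep(0, 5))   # 5 of 10 genomes present
spec <- community_spec(n_species = 10, abundances = ab,
                       genome_length = 2e4, coverage = 20, seed = 7)
comm <- generate_community(spec)
reads <- sample_reads(comm)

res <- run_end_to_end(reads$fastq, comm$genome_paths, comm$taxonomy,
                      sample_id = "demo")
res$containment
res$evidence
compare_profiles(comm$truth, res$profile, "species")
```

## Limitations

The package profiles relative abundance only; it performs no per-read
classification or binning, no genome-coverage-based presence evidence, and
no strain-resolution beyond carrying strain taxids through `TAXPATH`. The
containment cutoff is an empirical default, not calibrated against average
nucleotide identity. Redistribution is single-pass; the discarded mass of
presence-rule casualties is not re-assigned. The sketch database is held in
memory and is meant for collections of hundreds to thousands of genomes,
not a full multi-hundred-gigabyte reference archive.
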