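---
title: "Methods: genome recovery and transcriptional statistics for low-diversity metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome recovery and transcriptional statistics for low-diversity metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Low-diversity environmental communities — acid mine drainage (AMD) being
the canonical case — pair one overwhelmingly dominant taxon (relative
abundance above 90%) with a tail of rare taxa below 1%. Two consequences
shape the computational workflow this package implements:

* at assembly time the dominant genome saturates memory and drowns the
  rare genomes' k-mer signal, so reads are **partitioned by k-mer depth**
  before assembly ("divide and conquer"): deep (dominant) and shallow
  (rare) fractions are assembled separately;
* expression levels are only comparable across taxa after normalizing
  each feature twice — within its genome, and against its gene dosage —
  which is what the **Relative Transcriptional Activity** and **Indicator
  Value** statistics do.

`amdscope` implements the bespoke stages of this workflow as tested,
reusable functions, together with a synthetic-community generator that
provides exact ground truth for every stage. External database lookups
(BLAST, phymmBL, KEGG/eggNOG annotation) are deliberately out of scope:
taxonomy labels and KO/COG annotations enter as optional inputs.

# The synthetic community generator

The generator is first-class, tested code, not a fixture. It emulates the
features of real AMD data that the downstream methods rely on, and nothing
more.

**Genomes.** `generate_genome()` simulates each genome from its own
order-3 Markov chain. Transition weights are drawn uniformly per seed and
then tilted so that the chain's *stationary* GC content equals the target
exactly (solved with `uniroot` on the stationary distribution); realized
GC is then within sampling noise of the target. Order 3 makes 4-mer usage
genome-specific, which is precisely the signal tetranucleotide binning
exploits; different seeds give distinguishable signatures, identical seeds
give identical signatures (a documented failure mode used to test
bin-count selection). Default GC values span 0.36–0.67, the range observed
across real AMD draft genomes.

**Gene models and expression.** `generate_community()` places
non-overlapping genes (default 500–1500 bp, gaps 50–400 bp) with random
strands, KO labels drawn per genome without replacement from a shared pool
(so orthologs can recur across genomes), a deterministic KO→category map,
and i.i.d. log-normal(0, 1) expression weights. The log-normal default
produces the right-skewed transcript pools under which IQR-based outlier
detection is meaningful; field data give no empirical expression
distribution to fit, so this is a modeling choice, not an inference.

**Reads.** `simulate_dna_reads()` draws pairs with probability
proportional to abundance × genome length (uniform coverage within a
genome), normal insert sizes, 2×101 bp mates, and i.i.d. substitution
errors; `simulate_cdna_reads()` draws single-end reads from gene intervals
with probability ∝ abundance × expression weight × gene length and returns
the exact per-gene sampling probabilities. Qualities are written as
constant Q30: quality modeling is not part of the methods under study, and
no indel or coverage-bias model is attempted. `fragment_genomes()` cuts
genomes into tiling fragments — the stand-in for assembly, so binning is
testable against known contig origins — with coverage = abundance ×
depth-constant under multiplicative log-normal noise (sdlog 0.1 by
default, giving coverage refinement a realistic spread).

What passing tests on these data do **not** show: robustness to indels,
chimeric assemblies, strain-level microheterogeneity, uneven coverage
(GC bias, origin-of-replication effects), or conserved inter-genome
sequence; real genomes share k-mers across taxa far more than independent
Markov chains do, so real mapping ambiguity will be higher.

# Read partitioning

`count_kmers()` counts every length-k window of every mate in canonical
form (lexicographic minimum of window and reverse complement); windows
containing non-ACGT symbols are skipped, matching standard k-mer-counter
behavior. k must be odd, avoiding self-reverse-complement ambiguity.

`partition_reads()` applies the published contract — k = 31, depth
threshold 15, reads shorter than 63 bp removed — with two details the
original description leaves open, resolved as follows:

* **per-read statistic = median** canonical k-mer count (robust to the
  handful of erroneous k-mers one sequencing error creates, and the
  convention of the k-mer toolkit the workflow delegated to); the
  threshold is applied as **≥ 15**;
* **pairs stay together**, scored by the maximum of the two mates'
  depths: downstream assembly is paired-end and splitting mates would
  destroy insert information. A pair is discarded only when both mates
  are below the length cutoff.

Both choices are recorded here as this package's interpretation rather
than asserted as the original authors' intent. Exactness is guaranteed by
construction (hash-table counts), and the test suite checks counts,
per-read medians and the full three-way partition against an
independently coded brute-force enumeration.

# Contig dereplication and overlap merging

`split_scaffolds()` breaks scaffolds at every run of one or more N,
trading lost scaffold joins for protection against chimeric connections.

`dereplicate()` is greedy longest-first clustering: a contig is removed
when it aligns — either strand, over its whole length (`short_coverage =
1`), at ≥ 98% identity — to a contig already kept. Identity is computed by
end-free-in-subject pairwise alignment (match 1, mismatch −1, linear gap
−2; identity = matches / alignment columns), with an exact-substring fast
path and a seed prefilter (six spaced exact 31-mers; at 98% identity the
chance that every seed is hit by a mismatch is negligible, while unrelated
sequences essentially never trigger a full alignment).

`merge_overlaps()` greedily joins suffix/prefix overlaps of ≥ 40 bp at
≥ 98% identity on either strand, iterating to fixpoint; at the default
cutoffs the 40 bp seed must match exactly (⌊40 × 0.02⌋ = 0 allowed
mismatches), so candidate overlaps are found by plain string search and
verified gaplessly over the full overlap. The highest-identity (then
longest) overlap merges first, so in a cyclic overlap chain the weakest
junction is the one left unmerged, and disagreeing overlap columns take
the longer contig's bases (higher expected coverage). Merging cannot loop:
every merge reduces the contig count by one. `pool_by_length()` applies
the historical 2 kb routing boundary (< 2000 bp short, ≥ 2000 bp long).

# Genome binning

`tnf_profiles()` computes, per contig of ≥ 3000 bp, the 136 canonical
tetranucleotide frequencies (each 4-mer pooled with its reverse
complement: 16 palindromes + 120 pairs), normalized to sum 1 — canonical
rather than raw 256 because contig strand is arbitrary. Profiles are
clustered with Ward linkage on Euclidean distances of the raw frequencies
(no standardization — the source workflow states none).

**Bin-count selection.** The original analysis chose its bin count by
visual inspection of an NMDS ordination, which is not testable. This
package instead cuts the Ward tree at every k in a user range and picks
the k maximizing mean silhouette width, while still reporting NMDS stress
per dimensionality as the ordination diagnostic; the chosen k can be
overridden (`fix_k`). NMDS itself (`nmds()`) is Kruskal stress-1 by
iterative majorization with monotone regression (vegan's `monoMDS`),
started from the metric configuration so results are reproducible.

**Refinement.** `refine_bins()` turns the manual "divergent coverage or
phylogeny" curation into a deterministic rule: a contig whose coverage
deviates from its bin median by more than 3 × MAD, or whose taxonomy label
conflicts with the bin majority, moves to the nearest compatible bin by
TNF centroid distance, or becomes unbinned if none qualifies. All
decisions use the statistics of the input assignment, so the result does
not depend on processing order. MAD is used (rather than SD) because bins
contain few contigs and coverage noise is multiplicative.

`flag_chimeras()` is a deliberately simplified stand-in for self-BLAST
screening: it reports contigs containing a second copy of a ≥ 500 bp
block at ≥ 98% identity on either strand, found by spaced exact 31-mer
seeds and verified by gapless identity — adequate for the
substitution-only synthetic data; indel-shifted repeats are outside its
detection model. `estimate_completeness()` is the core-gene ratio
|observed ∩ core| / |core| against a user-supplied core-gene set, and
`relative_abundance()` is the mapped-read fraction per bin with the
unmapped remainder reported so fractions sum to one. Note that
read-fraction abundance weights cell abundance by genome length; the
pipeline's evaluation compares against that expectation.

# Transcriptional statistics

`map_reads_to_features()` is a deterministic exact-seed mapper sufficient
for the synthetic, low-error setting: a read is assigned to the unique
reference holding an exact canonical 31-mer match to the read's first
(else last) k-mer; multi-reference seeds discard the read as ambiguous,
and gene credit goes to the gene containing the mapped interval's
midpoint. It is plumbing, not a contribution — real data would use a
production aligner, and the expression functions accept external count
tables via `expression_table_from_counts()`.

For feature *a* in genome *b*, with shares taken against the genome's
total of feature-mapped reads (whether intergenic reads belong in the
denominator is unstated in the source; both totals are computed,
feature-mapped is the default):

* **RTA**: `RTA_ab = cDNA_ab / DNA_ab`, the ratio of the feature's cDNA
  share to its DNA share. When a feature has cDNA but zero DNA reads the
  ratio is undefined; 0.5 is added to both counts and the value flagged
  (`pseudo`). Features with no reads at all are NA with a reason. Genomes
  with zero totals are excluded, mirroring the treatment of taxa with too
  little associated information.
* **Outliers**: within each genome, features with cDNA count above
  Q3 + 1.5 × IQR (quartiles by linear interpolation, the common type-7
  convention — recorded because flags depend on it). The source text
  ("> 1.5 times the interquartile range") is ambiguous between this
  standard boxplot fence and a literal 1.5 × IQR threshold; both are
  implemented (`mode = "fence"` default, `"literal"` behind the switch).
* **Indicator Value**: `IV_ab = 100 · cDNA_ab / Σ_j cDNA_aj` over all g
  genomes — the concentration of the feature's relative expression in
  genome *b*, in the Dufrêne–Legendre indicator-value style, consistent
  with "IV > 50" meaning majority concentration. Σ_b IV_ab = 100 for
  every expressed feature by construction. **Indicator KOs** are outliers with IV
  strictly greater than 50.
* **Cross-taxon contrasts**: per functional category and genome, a
  two-sample Wilcoxon rank-sum test of the genome's RTA values against
  all other genomes' values in that category (exact null for small
  tie-free samples, normal approximation with tie correction otherwise,
  via `stats::wilcox.test`); flagged as overrepresented when p < 0.05 and
  the genome's median is higher. No multiple-testing correction is
  applied, matching the source analysis.
* **Profiles and rankings**: `category_rta()` averages RTA over a
  category's features; `zscore_profile()` centers and scales each
  category row across taxa with the population (n-denominator) SD —
  normalization over a fixed, complete set of taxa, not a sample estimate
  — zero-variance rows becoming flagged zeros. `top_expressed()` ranks
  features by RTA with deterministic tie-breaks (higher cDNA count, then
  feature id).

# Pipeline, determinism and problem sizes

`run_pipeline()` executes synthesize → partition → merge → bin → profile
from a single validated config (`pipeline_config()`, YAML round-trip via
`read_config()`/`write_config()`). Every random choice derives from the
config seed; the manifest records an MD5 checksum per output file and
contains no timestamps or absolute paths, so a rerun of the same config is
byte-identical — the package's reproducibility contract, asserted in the
test suite. Per-stage timings go to a separate log that is not
checksummed. Deleting a stage's outputs and rerunning just that stage
regenerates them identically, because each stage can reload its inputs
from the previous stage's files (or regenerate the deterministic truth).

The bundled demo community was sized to exercise every stage meaningfully
on a laptop: a 100 kb dominant genome at 91% abundance — small, so that
30 000 read pairs give it ~55× coverage and a median k-mer depth well
above the partition threshold — and four 400 kb rare genomes at 3/3/2/1%,
large enough to yield tens of 5–20 kb contigs each for binning while
staying below 1.5× coverage (cleanly in the low-abundance partition). The
standard binning test fixture uses five 550 kb genomes with GC evenly
spaced over 0.36–0.67, ≥ 40 contigs of 5–20 kb per genome; expression
recovery uses five equal-abundance genomes × 50 genes with 100 000 cDNA
reads, under which the per-genome Spearman correlation between estimated
RTA and true expression weight exceeds 0.9 and the uniform-expression
null gives median RTA within [0.9, 1.1].

# Numerical conventions and edge cases

* Canonical k-mers compare lexicographically over A < C < G < T; k even
  is rejected (a k-mer could equal its own reverse complement).
* Quantiles: type 7 everywhere; MAD with the standard 1.4826 consistency
  constant.
* `nmds()` requires a symmetric, non-negative, zero-diagonal matrix;
  stress is non-increasing in the embedding dimension (tested at 1–3).
* Degenerate inputs: genomes with fewer than 4 features are skipped by
  outlier detection (warning); categories with fewer than 2 observations
  per group yield NA p-values with a reason; `top_expressed()` returns
  all features with a warning when fewer than n have defined RTA;
  all-zero IV denominators give IV 0.
* Ties: dereplication order is longest-first then input order;
  merge candidates order by identity then overlap length; bin-count
  selection takes the smallest k at a tied silhouette; `top_expressed()`
  breaks ties by cDNA count then feature id.

# Known limitations

* The generator's independence assumptions (no shared sequence between
  genomes, substitution-only errors) make mapping and dereplication
  easier than on real data; results on synthetic fixtures bound what the
  methods can do, not what real assemblies will do.
* The exact-seed mapper ignores indels and paired-end constraints and is
  not a substitute for a production aligner on real reads.
* Silhouette-based bin-count selection can undercount when genomes share
  compositional signatures (tested as a documented failure mode); the
  pipeline accepts a fixed k for that case.
* The IV and RTA formulas are reconstructions from prose descriptions of
  the method; the reconstruction is recorded above, not asserted as
  exact.
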