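# amdscope

Genome reconstruction and transcriptional profiling for **low-diversity
metagenomes** — communities like acid mine drainage (AMD) in which a single
dominant taxon (relative abundance > 90%) coexists with many rare taxa
(< 1%). In such data the dominant genome drowns out the rare ones at
assembly time, and expression analyses must be normalized per taxon before
cross-taxon comparison is meaningful.

`amdscope` reimplements, as tested reusable R functions, the bespoke
computational stages of a combined metagenomic + metatranscriptomic
workflow:

1. **"Divide and conquer" read partitioning** — count canonical 31-mers
   over the read pool and split read pairs into high- and low-abundance
   groups by median k-mer depth (depth ≥ 15, reads < 63 bp removed), so
   dominant and rare genomes can be assembled separately.
2. **Contig post-processing** — split scaffolds at N-runs, remove
   redundant contigs (greedy longest-first dereplication at 98% identity,
   full coverage of the shorter sequence, both strands), and greedily merge
   contigs sharing suffix/prefix overlaps of ≥ 40 bp at ≥ 98% identity.
3. **Tetranucleotide-frequency (TNF) genome binning** — 136 canonical
   4-mer frequencies per contig (≥ 3000 bp), Ward/Euclidean hierarchical
   clustering, bin count chosen by silhouette maximization with NMDS
   stress as an ordination diagnostic, then coverage (median ± 3×MAD) and
   taxonomy refinement, internal-repeat (chimera) flagging, core-gene
   completeness, and read-mapping relative abundance.
4. **Per-taxon transcriptional statistics** — for each feature *a* (gene,
   KO or COG) in genome *b*:

   - relative abundance: share of the genome's mapped cDNA (or DNA) reads,
     `cDNA_ab = cdna count / genome cDNA total`;
   - **Relative Transcriptional Activity**: `RTA_ab = cDNA_ab / DNA_ab`
     (RTA = 1 ⇔ transcription proportional to gene dosage);
   - **expression outliers**: cDNA count > Q3 + 1.5×IQR within the genome;
   - **Indicator Value**: `IV_ab = 100 · cDNA_ab / Σ_j cDNA_aj` over all
     *g* genomes (Σ_b IV_ab = 100);
   - **indicator KOs**: expression outliers with IV > 50 (strict);
   - Wilcoxon rank-sum contrasts of RTA per functional category across
     taxa, z-scored category activity profiles, and top-N expressed-gene
     rankings.
5. **Synthetic community generator** — order-3 Markov genomes with
   calibrated GC (0.36–0.67, as in real AMD draft genomes), dominant+rare
   abundance profiles, non-overlapping gene models with log-normal
   expression weights, and paired-end 2×101 bp DNA / cDNA read simulation
   with exact ground truth, so every stage above is testable end to end.

## Worked example

```r
library(amdscope)

# a 5-genome community: one dominant (91%), four rare taxa
gcs <- seq(0.36, 0.67, length.out = 5)
specs <- lapply(1:5, function(i)
  genome_spec(paste0("g", i), 550000, gcs[i], markov_order = 3, seed = 50 + i))
truth <- generate_community(specs, c(0.91, 0.03, 0.03, 0.02, 0.01),
                            genes_per_genome = 10, seed = 8)
contigs <- fragment_genomes(truth, c(5000, 20000), seed = 9)

profiles <- tnf_profiles(contigs, min_len = 3000)
sel <- select_bin_count(profiles, 2, 10)
sel$k
#> [1] 5
head(sel$diagnostics, 5)
#>   k silhouette      stress
#> 1 2  0.5172707 0.007775816
#> 2 3  0.5439162 0.007090086
#> 3 4  0.5666786 0.006917735
#> 4 5  0.6678524 0.006044859
#> 5 6  0.5699714 0.005777015

asg <- cluster_contigs(profiles, sel$k)
org <- contigs$origin[match(rownames(profiles), contigs$contig_id)]
mclust::adjustedRandIndex(org, asg$bins)
#> [1] 1
```

The silhouette profile peaks at k = 5 — the true genome number — and the
Ward/TNF cut reproduces the genome-of-origin partition exactly (ARI 1):
with GC contents spread over 0.36–0.67, tetranucleotide signatures separate
cleanly at these contig lengths.

The whole workflow (synthesize → partition → merge → bin → profile) runs
from one declarative config:

```r
cfg <- pipeline_config()          # bundled demo community
run_pipeline(cfg, "demo_run")
evaluate_against_truth("demo_run")
#>                    metric       value
#> 1                 bin_ari 0.959438847
#> 2              bin_purity 0.985074627
#> 3 abundance_max_abs_error 0.004121522
#> 4            rta_spearman 0.876149149
#> 5     indicator_precision 1.000000000
#> 6        indicator_recall 1.000000000
```

A thin shell wrapper is installed at `inst/scripts/amdscope`
(`amdscope run --demo --out RUNDIR`, `amdscope evaluate --run RUNDIR`).

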