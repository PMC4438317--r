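Package: amdscope
Title: Genome Reconstruction and Transcriptional Profiling of Low-Diversity
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recovering dominant and rare genomes from combined
    metagenomic and metatranscriptomic sequencing of low-diversity microbial
    communities such as acid mine drainage. Implements a "divide and conquer"
    k-mer-depth read partitioning stage, scaffold splitting and greedy contig
    dereplication and overlap merging, tetranucleotide-frequency (TNF) genome
    binning with silhouette-based bin-count selection and coverage/taxonomy
    refinement, and per-taxon transcriptional statistics: Relative
    Transcriptional Activity (RTA), IQR-based expression outliers, Indicator
    Values and indicator-KO calls, Wilcoxon rank-sum contrasts, z-score
    activity profiles and top-expressed-gene rankings. A synthetic community
    generator with known ground truth (genomes, gene models, expression
    weights, paired-end DNA and cDNA reads) makes every stage testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    cluster,
    data.table,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
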