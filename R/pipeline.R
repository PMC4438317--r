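#' Build and validate a pipeline configuration
#'
#' A declarative description of one end-to-end run: community composition,
#' sequencing effort, and the stage parameters (k-mer partitioning,
#' dereplication/merging cutoffs, binning length cutoff and k range,
#' expression statistics options). Every random choice is governed by
#' `seed`; there are no wall-clock defaults, so a config reproduces its run
#' exactly. Configs round-trip through YAML unchanged via [write_config()]
#' and [read_config()].
#'
#' The default community emulates the abundance structure of interest: one
#' dominant genome at 91% and four rare genomes at 3/3/2/1%, GC contents
#' spanning 0.36--0.67.
#'
#' @param genomes data.frame(name, length, gc, markov_order, seed) of
#'   genome specs.
#' @param abundances numeric vector summing to 1, one entry per genome.
#' @param genes_per_genome,n_dna_pairs,n_cdna_reads simulation sizes.
#' @param read_len,insert_mean,insert_sd,error_rate read simulation
#'   parameters.
#' @param k,depth_threshold,min_read_len k-mer partitioning parameters.
#' @param derep_identity,merge_identity,min_overlap contig processing
#'   cutoffs.
#' @param fragment_len contig fragment length (single value or (min, max)).
#' @param depth_const,coverage_noise_sd synthetic coverage model.
#' @param min_contig_len TNF binning length cutoff.
#' @param k_min,k_max bin-count search range; `fix_k` overrides selection.
#' @param iqr_mode,alpha expression statistics options.
#' @param seed master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    genomes = data.frame(
      name = c("dom1", "rare1", "rare2", "rare3", "rare4"),
      length = c(100000L, rep(400000L, 4L)),
      gc = c(0.515, 0.36, 0.4375, 0.5925, 0.67),
      markov_order = 3L, seed = 101:105),
    abundances = c(0.91, 0.03, 0.03, 0.02, 0.01),
    genes_per_genome = 25L, n_dna_pairs = 30000L, n_cdna_reads = 20000L,
    read_len = 101L, insert_mean = 500, insert_sd = 50, error_rate = 0,
    k = 31L, depth_threshold = 15L, min_read_len = 63L,
    derep_identity = 0.98, merge_identity = 0.98, min_overlap = 40L,
    fragment_len = c(5000L, 20000L), depth_const = 1000,
    coverage_noise_sd = 0.1,
    min_contig_len = 3000L, k_min = 2L, k_max = 8L, fix_k = NULL,
    iqr_mode = "fence", alpha = 0.05, seed = 1L) {
  cfg <- list(genomes = as.data.frame(genomes), abundances = abundances,
              genes_per_genome = genes_per_genome,
              n_dna_pairs = n_dna_pairs, n_cdna_reads = n_cdna_reads,
              read_len = read_len, insert_mean = insert_mean,
              insert_sd = insert_sd, error_rate = error_rate,
              k = k, depth_threshold = depth_threshold,
              min_read_len = min_read_len,
              derep_identity = derep_identity,
              merge_identity = merge_identity, min_overlap = min_overlap,
              fragment_len = fragment_len, depth_const = depth_const,
              coverage_noise_sd = coverage_noise_sd,
              min_contig_len = min_contig_len,
              k_min = k_min, k_max = k_max, fix_k = fix_k,
              iqr_mode = iqr_mode, alpha = alpha, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  assert_that(nrow(cfg$genomes) == length(cfg$abundances),
              "one abundance per genome required")
  assert_that(abs(sum(cfg$abundances) - 1) <= 1e-9,
              "abundances must sum to 1")
  assert_that(cfg$k %% 2 == 1 && cfg$k >= 3 && cfg$k <= 63,
              "k must be odd and in [3, 63]")
  assert_that(cfg$depth_threshold >= 0, "depth_threshold must be >= 0")
  assert_that(cfg$min_read_len >= 1, "min_read_len must be >= 1")
  assert_that(cfg$derep_identity > 0.9 && cfg$derep_identity <= 1,
              "derep_identity must lie in (0.9, 1]")
  assert_that(cfg$merge_identity > 0 && cfg$merge_identity <= 1 &&
              cfg$min_overlap >= 1, "invalid merge parameters")
  assert_that(cfg$error_rate >= 0 && cfg$error_rate <= 0.1,
              "error_rate must lie in [0, 0.1]")
  assert_that(cfg$iqr_mode %in% c("fence", "literal"),
              "iqr_mode must be 'fence' or 'literal'")
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  assert_that(is.numeric(cfg$seed) && length(cfg$seed) == 1,
              "seed must be a single integer")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  out$genomes <- as.list(as.data.frame(cfg$genomes))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$genomes <- as.data.frame(raw$genomes, stringsAsFactors = FALSE)
  do.call(pipeline_config, raw)
}

truth_from_config <- function(cfg) {
  specs <- lapply(seq_len(nrow(cfg$genomes)), function(i)
    genome_spec(cfg$genomes$name[i], cfg$genomes$length[i],
                cfg$genomes$gc[i], cfg$genomes$markov_order[i],
                cfg$genomes$seed[i]))
  generate_community(specs, cfg$abundances,
                     genes_per_genome = cfg$genes_per_genome,
                     seed = cfg$seed)
}

#' Run the full workflow
#'
#' Executes the five stages in order -- synthesize, partition, merge, bin,
#' profile -- each stage reading the previous stage's outputs from the run
#' directory, and writes a manifest recording parameters, seeds and an MD5
#' checksum of every output file. Reruns with the same config produce
#' byte-identical outputs and manifests. A stage failure stops the run with
#' the stage named; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing stage outputs are
#'   overwritten).
#' @param stages subset of stages to run (default all, in order).
#' @return `out_dir`, invisibly. Side effects: stage subdirectories
#'   `01_synth` .. `05_express`, `config.yaml`, `manifest.tsv` and
#'   `log.tsv` (per-stage timing and record counts; not checksummed).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("synth", "partition", "merge", "bin",
                                    "express")) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  state <- new.env(parent = emptyenv())
  logrows <- list()
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    logrows[[length(logrows) + 1L]] <<- data.frame(
      stage = name, seconds = round(as.numeric(Sys.time() - t0, "secs"), 2),
      records = res %||% NA_integer_)
    invisible(NULL)
  }

  run_stage("synth", function() stage_synth(config, out_dir, state))
  run_stage("partition", function() stage_partition(config, out_dir, state))
  run_stage("merge", function() stage_merge(config, out_dir, state))
  run_stage("bin", function() stage_bin(config, out_dir, state))
  run_stage("express", function() stage_express(config, out_dir, state))

  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    c("manifest.tsv", "log.tsv")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv(do.call(rbind, logrows), file.path(out_dir, "log.tsv"))
  invisible(out_dir)
}

stage_dir <- function(out_dir, name) {
  d <- file.path(out_dir, name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

stage_synth <- function(cfg, out_dir, state) {
  d <- stage_dir(out_dir, "01_synth")
  truth <- truth_from_config(cfg)
  dna <- simulate_dna_reads(truth, cfg$n_dna_pairs, cfg$read_len,
                            cfg$insert_mean, cfg$insert_sd,
                            cfg$error_rate, seed = cfg$seed + 1L)
  cdna <- simulate_cdna_reads(truth, cfg$n_cdna_reads, cfg$read_len,
                              cfg$error_rate, seed = cfg$seed + 2L)
  write_truth(truth, file.path(d, "truth"))
  write_fastq(dna, file.path(d, "dna"))
  write_fastq(cdna, file.path(d, "cdna"))
  write_tsv(data.frame(read_id = dna$read_id, origin = dna$origin,
                       start = dna$start),
            file.path(d, "dna_truth.tsv"))
  write_tsv(data.frame(read_id = cdna$read_id, origin = cdna$origin,
                       gene_id = cdna$gene_id, start = cdna$start),
            file.path(d, "cdna_truth.tsv"))
  write_tsv(attr(cdna, "gene_probs"), file.path(d, "cdna_gene_probs.tsv"))
  state$truth <- truth; state$dna <- dna; state$cdna <- cdna
  nrow(dna) + nrow(cdna)
}

stage_partition <- function(cfg, out_dir, state) {
  d <- stage_dir(out_dir, "02_partition")
  dna <- state$dna %||% read_fastq_pairs(
    file.path(out_dir, "01_synth", "dna_1.fastq"),
    file.path(out_dir, "01_synth", "dna_2.fastq"))
  tab <- count_kmers(dna, cfg$k)
  part <- partition_reads(dna, tab, cfg$depth_threshold, cfg$min_read_len)
  for (grp in c("high", "low")) write_fastq(part[[grp]],
                                            file.path(d, grp))
  if (nrow(part$discarded))
    write_fastq(part$discarded, file.path(d, "discarded"))
  bases <- function(rs) sum(nchar(rs$mate1), nchar(rs$mate2), na.rm = TRUE)
  write_tsv(data.frame(
    group = c("high", "low", "discarded"),
    pairs = c(nrow(part$high), nrow(part$low), nrow(part$discarded)),
    bases = c(bases(part$high), bases(part$low), bases(part$discarded))),
    file.path(d, "summary.tsv"))
  state$partition <- part
  nrow(part$high) + nrow(part$low)
}

stage_merge <- function(cfg, out_dir, state) {
  d <- stage_dir(out_dir, "03_merge")
  truth <- state$truth %||% truth_from_config(cfg)
  contigs <- fragment_genomes(truth, cfg$fragment_len,
                              depth = cfg$depth_const,
                              coverage_noise_sd = cfg$coverage_noise_sd,
                              seed = cfg$seed + 3L)
  contigs <- split_scaffolds(contigs)
  derep <- dereplicate(contigs, cfg$derep_identity)
  merged <- merge_overlaps(derep, cfg$merge_identity, cfg$min_overlap)
  pools <- pool_by_length(merged, 2000L)
  write_contigs(merged, file.path(d, "contigs"))
  write_tsv(attr(derep, "clusters"), file.path(d, "derep_clusters.tsv"))
  write_tsv(data.frame(pool = c("short", "long"),
                       n = c(nrow(pools$short), nrow(pools$long))),
            file.path(d, "pools.tsv"))
  state$contigs <- merged
  nrow(merged)
}

stage_bin <- function(cfg, out_dir, state) {
  d <- stage_dir(out_dir, "04_bin")
  contigs <- state$contigs %||% read_contigs(file.path(out_dir, "03_merge",
                                                       "contigs"))
  profiles <- tnf_profiles(contigs, cfg$min_contig_len)
  if (is.null(cfg$fix_k)) {
    sel <- select_bin_count(profiles, cfg$k_min, cfg$k_max,
                            nmds_seed = cfg$seed)
    write_tsv(sel$diagnostics, file.path(d, "k_diagnostics.tsv"))
    k <- sel$k
  } else k <- cfg$fix_k
  assignment <- cluster_contigs(profiles, k)
  coverage <- setNames(contigs$coverage, contigs$contig_id)
  refined <- refine_bins(assignment, profiles, coverage,
                         taxonomy = setNames(contigs$taxonomy,
                                             contigs$contig_id))
  membership <- data.frame(contig_id = names(refined$bins),
                           bin = refined$bins,
                           origin = contigs$origin[
                             match(names(refined$bins), contigs$contig_id)])
  write_tsv(membership, file.path(d, "membership.tsv"))
  write_tsv(bin_summary(refined, contigs), file.path(d, "bin_summary.tsv"))
  dna <- state$dna %||% read_fastq_pairs(
    file.path(out_dir, "01_synth", "dna_1.fastq"),
    file.path(out_dir, "01_synth", "dna_2.fastq"))
  mapping <- map_reads_to_contigs(dna, contigs, cfg$k)
  ab <- relative_abundance(mapping, refined)
  write_tsv(data.frame(bin = names(ab), fraction = as.numeric(ab)),
            file.path(d, "abundance.tsv"))
  chim <- flag_chimeras(contigs)
  write_tsv(chim, file.path(d, "chimera_flags.tsv"))
  state$assignment <- refined
  length(refined$bins)
}

stage_express <- function(cfg, out_dir, state) {
  d <- stage_dir(out_dir, "05_express")
  truth <- state$truth %||% truth_from_config(cfg)
  dna <- state$dna %||% read_fastq_pairs(
    file.path(out_dir, "01_synth", "dna_1.fastq"),
    file.path(out_dir, "01_synth", "dna_2.fastq"))
  cdna <- state$cdna %||% read_fastq_pairs(
    file.path(out_dir, "01_synth", "cdna.fastq"))
  sidx <- build_seed_index(truth$genomes, cfg$k)
  dna_map <- map_reads_to_features(dna, truth$genomes, truth$genes, cfg$k,
                                   index = sidx)
  cdna_map <- map_reads_to_features(cdna, truth$genomes, truth$genes,
                                    cfg$k, index = sidx)
  for (lvl in c("gene", "KO")) {
    tab <- expression_table(dna_map, cdna_map, truth$genes, lvl)
    r <- rta(tab)
    write_tsv(as.data.frame(r),
              file.path(d, sprintf("rta_%s.tsv", tolower(lvl))))
    if (lvl == "KO") {
      outl <- detect_outliers(tab, mode = cfg$iqr_mode)
      ivs <- indicator_value(tab)
      ind <- identify_indicators(outl, ivs)
      write_tsv(ind, file.path(d, "indicators.tsv"))
      cats <- unique(truth$genes[, c("ko", "category")])
      names(cats) <- c("feature", "category")
      cmp <- compare_rta(r, cats, cfg$alpha)
      write_tsv(cmp, file.path(d, "category_tests.tsv"))
      z <- zscore_profile(category_rta(r, cats))
      write_tsv(data.frame(category = rownames(z), as.data.frame(z)),
                file.path(d, "zscore_profile.tsv"))
      top <- suppressWarnings(top_expressed(r, 10L))
      write_tsv(top, file.path(d, "top_expressed.tsv"))
    }
  }
  nrow(truth$genes)
}

#' Evaluate a run against its ground truth
#'
#' Scores a completed synthetic run: bin Adjusted Rand Index and purity
#' against the contigs' true origins, the largest absolute error of the
#' read-mapping abundance estimates, the mean per-genome Spearman
#' correlation between gene-level RTA and the true expression weights, and
#' precision/recall of indicator-KO calls against the indicator set
#' implied by the expected (noise-free) read counts.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return data.frame(metric, value), also written to
#'   `<run_dir>/metrics.tsv`.
#' @export
evaluate_against_truth <- function(run_dir) {
  cfgf <- file.path(run_dir, "config.yaml")
  assert_that(file.exists(cfgf), "no config.yaml in %s", run_dir)
  cfg <- read_config(cfgf)
  truth_dir <- file.path(run_dir, "01_synth", "truth")
  assert_that(dir.exists(truth_dir), "missing truth files in %s", run_dir)
  genes <- read_tsv(file.path(truth_dir, "genes.tsv"))
  abund <- read_tsv(file.path(truth_dir, "abundances.tsv"))

  membership <- read_tsv(file.path(run_dir, "04_bin", "membership.tsv"))
  binned <- membership[!is.na(membership$bin), ]
  ari <- mclust::adjustedRandIndex(binned$origin, binned$bin)
  purity <- sum(vapply(split(binned$origin, binned$bin),
                       function(o) max(table(o)), 0)) / nrow(binned)

  ab <- read_tsv(file.path(run_dir, "04_bin", "abundance.tsv"))
  majority <- vapply(split(binned$origin, binned$bin),
                     function(o) names(sort(table(o), decreasing = TRUE))[1L],
                     "")
  est <- tapply(ab$fraction[match(paste0("bin_", names(majority)), ab$bin)],
                majority, sum)
  true_ab <- setNames(abund$abundance, abund$genome)
  # read-mapping abundance estimates each genome's DNA share (abundance
  # weighted by genome length) restricted to its binned contigs, which is
  # what a read fraction over bins measures
  glen <- nchar(read_fasta(file.path(truth_dir, "genomes.fasta")))
  contigs_meta <- read_tsv(file.path(run_dir, "03_merge", "contigs.tsv"))
  binned_len <- tapply(
    contigs_meta$length[match(binned$contig_id, contigs_meta$contig_id)],
    binned$origin, sum)
  read_frac <- true_ab * glen[names(true_ab)]
  read_frac <- read_frac / sum(read_frac)
  expected <- read_frac * binned_len[names(read_frac)] /
    glen[names(read_frac)]
  ab_err <- max(abs(est[names(expected)] - expected), na.rm = TRUE)

  rta_gene <- read_tsv(file.path(run_dir, "05_express", "rta_gene.tsv"))
  m <- merge(rta_gene, genes[, c("gene_id", "genome", "weight")],
             by.x = c("feature", "genome"), by.y = c("gene_id", "genome"))
  rho <- mean(vapply(split(m, m$genome), function(d)
    suppressWarnings(cor(d$rta, d$weight, method = "spearman",
                         use = "complete.obs")), 0), na.rm = TRUE)

  ind <- read_tsv(file.path(run_dir, "05_express", "indicators.tsv"))
  truth_ind <- expected_indicators(cfg, genes, true_ab)
  called <- paste(ind$feature, ind$genome)[ind$indicator]
  expected <- paste(truth_ind$feature, truth_ind$genome)[truth_ind$indicator]
  precision <- if (length(called)) mean(called %in% expected) else NA_real_
  recall <- if (length(expected)) mean(expected %in% called) else NA_real_

  metrics <- data.frame(
    metric = c("bin_ari", "bin_purity", "abundance_max_abs_error",
               "rta_spearman", "indicator_precision", "indicator_recall"),
    value = c(ari, purity, ab_err, rho, precision, recall))
  write_tsv(metrics, file.path(run_dir, "metrics.tsv"))
  metrics
}

# The indicator set implied by expected (infinite-depth) counts: expected
# cDNA counts proportional to the true per-gene sampling probabilities,
# expected DNA counts proportional to abundance x gene length.
expected_indicators <- function(cfg, genes, true_ab) {
  glen <- genes$end - genes$start + 1L
  cdna_prob <- true_ab[genes$genome] * genes$weight * glen
  cdna_prob[glen < cfg$read_len] <- 0
  cdna_prob <- cdna_prob / sum(cdna_prob)
  dna_prob <- true_ab[genes$genome] * glen
  dna_prob <- dna_prob / sum(dna_prob)
  df <- data.frame(feature = genes$ko, genome = genes$genome,
                   dna_count = dna_prob * cfg$n_dna_pairs * 2,
                   cdna_count = cdna_prob * cfg$n_cdna_reads)
  dt <- as.data.table(df)[, list(dna_count = sum(dna_count),
                                 cdna_count = sum(cdna_count)),
                          by = c("feature", "genome")]
  tab <- expression_table_from_counts(as.data.frame(dt))
  identify_indicators(detect_outliers(tab, mode = cfg$iqr_mode),
                      indicator_value(tab))
}
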