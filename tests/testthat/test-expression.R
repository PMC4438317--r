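# small hand-built count table used across several blocks
toy_table <- function() {
  counts <- expand.grid(feature = sprintf("K%02d", 1:5),
                        genome = c("gA", "gB"),
                        stringsAsFactors = FALSE)
  counts$dna_count <- c(10, 10, 10, 10, 10, 20, 20, 20, 20, 20)
  counts$cdna_count <- c(5, 5, 5, 5, 100, 8, 8, 8, 8, 8)
  expression_table_from_counts(counts)
}

test_that("exact seed mapping assigns reads to the right genes and genomes", {
  truth <- fx_small_truth()
  g <- truth$genes[3, ]
  inside <- substr(truth$genomes[[g$genome]], g$start, g$start + 100)
  # intergenic window: before the first gene
  first <- min(truth$genes$start[truth$genes$genome == g$genome])
  inter <- substr(truth$genomes[[g$genome]], 2, 102)
  stopifnot(first > 110)
  rs <- amdscope:::new_read_set(data.frame(
    read_id = c("in_gene", "intergenic", "rc_in_gene"),
    mate1 = c(inside, inter, amdscope:::revcomp(inside)),
    mate2 = NA_character_, stringsAsFactors = FALSE), 101)
  m <- map_reads_to_features(rs, truth$genomes, truth$genes)
  rm <- m$read_map
  expect_equal(rm$gene_id[rm$read_id == "in_gene/1"], g$gene_id)
  expect_equal(rm$gene_id[rm$read_id == "rc_in_gene/1"], g$gene_id)
  expect_true(is.na(rm$gene_id[rm$read_id == "intergenic/1"]))
  expect_equal(rm$genome[rm$read_id == "intergenic/1"], g$genome)
  tot <- m$totals
  expect_equal(tot$mapped_reads[tot$genome == g$genome], 3L)
  expect_equal(tot$gene_reads[tot$genome == g$genome], 2L)
})

test_that("mapped cDNA counts follow the true sampling probabilities", {
  fx <- fx_expr()
  truth <- fx$truth
  cdna <- simulate_cdna_reads(truth, 10000, seed = 55)
  probs <- attr(cdna, "gene_probs")
  m <- map_reads_to_features(cdna, truth$genomes, truth$genes)
  cnt <- m$counts[!is.na(m$counts$gene_id), ]
  got <- setNames(cnt$count, cnt$gene_id)
  # 3-sigma binomial envelope per gene
  ok <- vapply(seq_len(nrow(probs)), function(i) {
    p <- probs$prob[i]
    n <- 10000
    x <- got[probs$gene_id[i]]
    if (is.na(x)) x <- 0
    abs(x - n * p) <= 3 * sqrt(n * p * (1 - p)) + 1e-9
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("relative abundances are count shares of genome totals", {
  tab <- expression_table_from_counts(
    data.frame(feature = c("f1", "f2", "f3", "f4"),
               genome = "g1", dna_count = c(5, 15, 20, 10),
               cdna_count = c(10, 10, 10, 10)))
  sh <- relative_abundances(tab)
  expect_equal(sh$dna_share, c(5, 15, 20, 10) / 50)
  expect_equal(sh$cdna_share, rep(0.25, 4))
  expect_lte(sum(sh$dna_share), 1 + 1e-12)
})

test_that("RTA is the cDNA/DNA share ratio with a flagged pseudocount fallback", {
  counts <- data.frame(feature = c("a", "b", "c", "d"),
                       genome = "g",
                       dna_count = c(10, 10, 0, 0),
                       cdna_count = c(10, 20, 30, 0))
  tot <- data.frame(genome = "g", dna_gene_total = 500, dna_all_total = 500,
                    cdna_gene_total = 500, cdna_all_total = 500)
  r <- rta(expression_table_from_counts(counts, tot))
  expect_equal(r$rta[r$feature == "a"], 1)      # equal shares
  expect_equal(r$rta[r$feature == "b"], 2)      # double the cDNA share
  expect_true(r$pseudo[r$feature == "c"])
  expect_equal(r$rta[r$feature == "c"], 30.5 / 0.5)
  expect_true(is.na(r$rta[r$feature == "d"]))
  expect_equal(r$undefined_reason[r$feature == "d"], "no_reads")
})

test_that("RTA recovers the planted expression weights", {
  fx <- fx_expr()
  tab <- expression_table(fx$dna_map, fx$cdna_map, fx$truth$genes, "gene")
  r <- rta(tab)
  m <- merge(as.data.frame(r), fx$truth$genes,
             by.x = c("feature", "genome"), by.y = c("gene_id", "genome"))
  rho <- vapply(split(m, m$genome), function(d)
    cor(d$rta, d$weight, method = "spearman", use = "complete.obs"), 0)
  expect_true(all(rho >= 0.9))
})

test_that("uniform expression gives median RTA near 1 in every genome", {
  fx <- fx_null()
  tab <- expression_table(fx$dna_map, fx$cdna_map, fx$truth$genes, "gene")
  r <- rta(tab)
  med <- tapply(r$rta, r$genome, median, na.rm = TRUE)
  expect_true(all(med >= 0.9 & med <= 1.1))
})

test_that("IQR outlier detection matches hand-computed fences", {
  counts <- data.frame(feature = sprintf("K%d", 1:5), genome = "g",
                       dna_count = 1, cdna_count = c(1, 1, 1, 1, 100))
  o <- detect_outliers(expression_table_from_counts(counts))
  # Q3 = 1, IQR = 0 -> fence 1; only the 100 exceeds it
  expect_equal(o$feature[o$outlier], "K5")
  flat <- data.frame(feature = sprintf("K%d", 1:6), genome = "g",
                     dna_count = 1, cdna_count = 7)
  expect_false(any(detect_outliers(expression_table_from_counts(flat))$outlier))
  small <- data.frame(feature = c("a", "b"), genome = "g",
                      dna_count = 1, cdna_count = c(1, 2))
  expect_warning(o2 <- detect_outliers(expression_table_from_counts(small)),
                 "skipped")
  expect_equal(nrow(o2), 0L)
})

test_that("outlier flags equal an independent quantile routine on random tables", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    counts <- data.frame(feature = sprintf("K%03d", 1:n), genome = "g",
                         dna_count = 1,
                         cdna_count = rpois(n, sample(c(2, 10, 50), 1)))
    o <- detect_outliers(expression_table_from_counts(counts))
    q1 <- oracle_quantile7(counts$cdna_count, 0.25)
    q3 <- oracle_quantile7(counts$cdna_count, 0.75)
    expected <- counts$cdna_count > q3 + 1.5 * (q3 - q1)
    expect_equal(o$outlier, expected)
  }
})

test_that("the literal 1.5xIQR reading is available behind the switch", {
  counts <- data.frame(feature = sprintf("K%d", 1:5), genome = "g",
                       dna_count = 1, cdna_count = c(0, 10, 20, 30, 41))
  # Q1=10, Q3=30, IQR=20: literal threshold 30, fence 60
  lit <- detect_outliers(expression_table_from_counts(counts),
                         mode = "literal")
  fen <- detect_outliers(expression_table_from_counts(counts))
  expect_equal(sum(lit$outlier), 1L)
  expect_equal(sum(fen$outlier), 0L)
})

test_that("indicator values concentrate, normalize and sum to 100", {
  tab <- toy_table()
  iv <- indicator_value(tab)
  # K05 expressed 100/120 in gA vs 8/40 in gB
  ivsums <- tapply(iv$iv, iv$feature, sum)
  expect_true(all(abs(ivsums - 100) < 1e-6))
  expect_true(all(iv$iv >= 0 & iv$iv <= 100))
  expect_equal(attr(iv, "g"), 2L)

  # a feature expressed in exactly one genome takes IV 100 there
  counts <- data.frame(feature = "K1", genome = c("a", "b", "c"),
                       dna_count = 1, cdna_count = c(50, 0, 0))
  iv1 <- indicator_value(expression_table_from_counts(counts))
  expect_equal(iv1$iv[iv1$genome == "a"], 100)
  expect_equal(sum(iv1$iv), 100)

  # equal shares across 4 genomes -> 25 each
  counts4 <- data.frame(feature = "K1", genome = letters[1:4],
                        dna_count = 1, cdna_count = 10)
  expect_equal(indicator_value(expression_table_from_counts(counts4))$iv,
               rep(25, 4))
})

test_that("indicator calls require outlier status and IV strictly above 50", {
  outl <- data.frame(feature = c("K1", "K2", "K3"), genome = "g",
                     cdna_count = 1, outlier = c(TRUE, TRUE, FALSE))
  ivs <- data.frame(feature = c("K1", "K2", "K3"), genome = "g",
                    iv = c(50, 100, 90))
  ind <- identify_indicators(outl, ivs)
  expect_equal(ind$indicator, c(FALSE, TRUE, FALSE))
})

test_that("a KO over-expressed in a rare genome is recovered as its indicator", {
  # 100x expression in the 1%-abundance genome vs 1x elsewhere
  genomes <- c("dom", "r1", "r2", "r3", "rare")
  background <- expand.grid(feature = sprintf("K%02d", 1:9),
                            genome = genomes, stringsAsFactors = FALSE)
  background$dna_count <- 50
  background$cdna_count <- rep(c(900, 110, 100, 90, 4), each = 9)
  planted <- data.frame(feature = "K_planted", genome = genomes,
                        dna_count = 50, cdna_count = c(1, 1, 1, 1, 100))
  tab <- expression_table_from_counts(rbind(background, planted))
  ind <- identify_indicators(detect_outliers(tab), indicator_value(tab))
  hit <- ind[ind$feature == "K_planted" & ind$genome == "rare", ]
  expect_true(hit$indicator)
  expect_false(any(ind$indicator[ind$feature == "K_planted" &
                                 ind$genome != "rare"]))
})

test_that("Wilcoxon contrasts flag separation and match exact enumeration", {
  # complete separation at n=10 vs 30 gives p < 0.001 and a flag
  r <- data.frame(feature = rep(sprintf("f%02d", 1:40)),
                  genome = rep(c("hot", "g2", "g3", "g4"), times = c(10, 10, 10, 10)),
                  rta = c(10 + runif(10), runif(30)))
  cats <- data.frame(feature = r$feature, category = "cat1")
  cmp <- compare_rta(structure(r, class = c("rta_result", "data.frame")),
                     cats)
  hot <- cmp[cmp$genome == "hot", ]
  expect_lt(hot$p, 0.001)
  expect_true(hot$overrepresented)

  # p-values match brute-force enumeration on random tie-free inputs
  set.seed(12)
  for (rep in 1:50) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    x <- rnorm(m); y <- rnorm(n)
    df <- data.frame(feature = sprintf("f%02d", seq_len(m + n)),
                     genome = rep(c("a", "b"), c(m, n)), rta = c(x, y))
    cats <- data.frame(feature = df$feature, category = "c")
    p_pkg <- compare_rta(structure(df, class = c("rta_result", "data.frame")),
                         cats)
    expect_equal(p_pkg$p[p_pkg$genome == "a"], oracle_wilcoxon(x, y),
                 tolerance = 1e-6)
  }

  # identical distributions are not flagged
  same <- data.frame(feature = sprintf("f%02d", 1:20),
                     genome = rep(c("a", "b"), each = 10),
                     rta = rep(1:10, 2))
  cats <- data.frame(feature = same$feature, category = "c")
  out <- compare_rta(structure(same, class = c("rta_result", "data.frame")),
                     cats)
  expect_false(any(out$overrepresented))
})

test_that("z-scoring centers rows with the population sd convention", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_profile(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(attr(z, "flat_rows"), "b")
  expect_true(all(abs(rowMeans(z)) < 1e-9))
})

test_that("top-expressed ranking is deterministic with documented tie-breaks", {
  r <- data.frame(feature = c("f1", "f2", "f3", "f4"), genome = "g",
                  rta = c(2, 2, 5, 1), cdna_count = c(10, 20, 5, 50))
  top <- top_expressed(structure(r, class = c("rta_result", "data.frame")),
                       n = 3)
  expect_equal(top$feature, c("f3", "f2", "f1"))
  expect_warning(
    all3 <- top_expressed(structure(r, class = c("rta_result", "data.frame")),
                          n = 10),
    "only 4")
  expect_equal(nrow(all3), 4L)
})

test_that("KOs shared by more genomes rank higher when built to do so", {
  # construct a community whose shared KOs carry boosted weights, then
  # check the estimated expression ranks preserve the planted trend
  truth <- fx_small_truth()
  genes <- truth$genes
  shared <- names(which(table(unique(genes[, c("genome", "ko")])$ko) > 1))
  t2 <- truth
  boost <- genes$ko %in% shared
  t2$genes$weight <- ifelse(boost, genes$weight * 8, genes$weight)
  cdna <- simulate_cdna_reads(t2, 30000, seed = 66)
  m <- map_reads_to_features(cdna, t2$genomes, t2$genes)
  cnt <- merge(m$counts[!is.na(m$counts$gene_id), ], t2$genes,
               by.x = c("genome", "gene_id"), by.y = c("genome", "gene_id"))
  rank_by_genome <- unlist(tapply(cnt$count, cnt$genome, rank))
  is_shared <- unlist(tapply(cnt$ko %in% shared, cnt$genome, identity))
  expect_gt(mean(rank_by_genome[is_shared]),
            mean(rank_by_genome[!is_shared]))
})
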