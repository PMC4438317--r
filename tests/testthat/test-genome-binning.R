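test_that("TNF profiles are canonical, normalized and oracle-equal", {
  polyA <- paste(rep("A", 3000), collapse = "")
  p <- tnf_profile(polyA)
  expect_equal(length(p), 136L)
  expect_equal(unname(p["AAAA"]), 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(tnf_profile("ACGT"), "cutoff")

  seqs <- vapply(1:5, function(i) generate_genome(
    genome_spec("g", 10000, 0.45 + 0.05 * i, 2, i))[1:1] , "")
  for (s in substring(seqs, 1, 5000)) {
    expect_equal(tnf_profile(s), tnf_profile(amdscope:::revcomp(s)))
    o <- oracle_tnf(s)
    mine <- tnf_profile(s)
    expect_equal(unname(mine[names(o)]), unname(o), tolerance = 1e-12)
    expect_equal(sum(mine[setdiff(names(mine), names(o))]), 0)
  }
})

test_that("Ward/TNF clustering recovers genome origins on the standard fixture", {
  pr <- fx_bin_profiles()
  ct <- fx_bin_contigs()
  expect_true(all(table(ct$origin) >= 40))
  org <- ct$origin[match(rownames(pr), ct$contig_id)]

  # trivial cuts
  n <- nrow(pr)
  expect_equal(length(unique(cluster_contigs(pr, 1)$bins)), 1L)
  expect_equal(length(unique(cluster_contigs(pr, n)$bins)), n)
  expect_error(cluster_contigs(pr, 0), "n_bins")

  sel <- select_bin_count(pr, 2, 10)
  expect_equal(sel$k, 5L)
  expect_equal(nrow(sel$diagnostics), 9L)
  asg <- cluster_contigs(pr, sel$k)
  ari <- mclust::adjustedRandIndex(org, asg$bins)
  expect_gte(ari, 0.90)
})

test_that("bin-count selection fails gracefully when signatures coincide", {
  # two of three genomes share a seed (identical signature): chosen k
  # falls below the genome count
  specs <- list(genome_spec("a", 150000, 0.45, 3, 91),
                genome_spec("b", 150000, 0.45, 3, 91),
                genome_spec("c", 150000, 0.65, 3, 93))
  truth <- generate_community(specs, c(0.4, 0.4, 0.2),
                              genes_per_genome = 5, seed = 30)
  frags <- fragment_genomes(truth, c(5000, 10000), seed = 31)
  pr <- tnf_profiles(frags)
  sel <- select_bin_count(pr, 2, 6)
  expect_lt(sel$k, 3)
})

test_that("NMDS embeds Euclidean configurations at near-zero stress", {
  # equilateral triangle embeds exactly in 2-D
  tri <- matrix(1, 3, 3) - diag(3)
  expect_lt(nmds(tri, dims = 2)$stress, 1e-3)
  # distances that are already 2-D Euclidean re-embed at stress < 0.01
  set.seed(3)
  pts <- matrix(rnorm(40), ncol = 2)
  d <- as.matrix(dist(pts))
  expect_lt(nmds(d, dims = 2)$stress, 0.01)
  # stress is non-increasing in embedding dimension
  pr <- fx_bin_profiles()[1:40, ]
  dd <- as.matrix(dist(pr))
  s1 <- nmds(dd, dims = 1)$stress
  s2 <- nmds(dd, dims = 2)$stress
  s3 <- nmds(dd, dims = 3)$stress
  expect_lte(s2, s1 + 1e-9)
  expect_lte(s3, s2 + 1e-9)
  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("refinement relocates coverage outliers and respects consistency", {
  pr <- fx_bin_profiles()
  ct <- fx_bin_contigs()
  org <- ct$origin[match(rownames(pr), ct$contig_id)]
  asg <- cluster_contigs(pr, 5)

  # consistent coverage and labels: nothing moves
  cov_const <- setNames(rep(10, nrow(pr)), rownames(pr))
  r0 <- refine_bins(asg, pr, cov_const)
  expect_identical(r0$bins, asg$bins)
  expect_equal(nrow(r0$moves), 0L)

  # plant a divergent-coverage contig: genome-A coverage (10x) inside a
  # 60x bin is moved out
  cov <- setNames(ifelse(org == org[1], 60, 10), rownames(pr))
  victim <- rownames(pr)[which(org == org[1])[1]]
  cov[victim] <- 10
  r1 <- refine_bins(asg, pr, cov)
  expect_true(victim %in% r1$moves$contig_id)
  expect_false(identical(r1$bins[victim], asg$bins[victim]))

  # conflicting taxonomy with no compatible destination -> unbinned
  tax <- setNames(org, rownames(pr))
  tax[victim] <- "alien_taxon"
  r2 <- refine_bins(asg, pr, cov_const, taxonomy = tax)
  expect_true(is.na(r2$bins[victim]))
})

test_that("internal repeats are flagged and clean contigs are not", {
  X <- generate_genome(genome_spec("x", 12000, 0.5, 3, 77))
  blk <- substr(X, 10001, 11000)
  backbone <- substr(X, 1, 8000)
  tandem <- paste0(substr(backbone, 1, 4000), blk, blk,
                   substr(backbone, 4001, 7000))
  f <- flag_chimeras(contig_set("t", tandem))
  expect_equal(nrow(f), 1L)
  expect_equal(f$strand, "+")
  # the reported spans cover copies of the same block
  expect_identical(substr(tandem, f$start1, f$end1),
                   substr(tandem, f$start2, f$end2))

  short_dup <- paste0(substr(backbone, 1, 4000), substr(blk, 1, 400),
                      substr(blk, 1, 400), substr(backbone, 4001, 7000))
  expect_equal(nrow(flag_chimeras(contig_set("s", short_dup))), 0L)

  # random contigs never trigger the screen
  clean <- vapply(1:20, function(i)
    generate_genome(genome_spec("c", 10000, 0.5, 3, 200 + i)), "")
  expect_equal(nrow(flag_chimeras(contig_set(paste0("c", 1:20), clean))),
               0L)
})

test_that("completeness is a set ratio, monotone under contig addition", {
  core <- sprintf("K%02d", 1:100)
  expect_equal(estimate_completeness(core, core), 1)
  expect_equal(estimate_completeness(core[1:53], core), 0.53)
  expect_equal(estimate_completeness(c(core[1:53], core[1:10]), core), 0.53)
  expect_error(estimate_completeness("K01", character(0)), "non-empty")
  # monotonicity
  set.seed(4)
  genes <- sample(core, 60)
  vals <- vapply(seq(10, 60, by = 10), function(n)
    estimate_completeness(genes[1:n], core), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("read-mapping abundances are conserved fractions per bin", {
  bins <- c(c1 = 1L, c2 = 1L, c3 = 2L)
  mapping <- data.frame(read_id = sprintf("r%d", 1:10),
                        contig_id = c(rep("c1", 4), rep("c2", 2),
                                      rep("c3", 3), NA))
  ab <- relative_abundance(mapping, bins)
  expect_equal(unname(ab["bin_1"]), 0.6)
  expect_equal(unname(ab["bin_2"]), 0.3)
  expect_equal(unname(ab["unmapped"]), 0.1)
  expect_equal(sum(ab), 1)
  # all reads in one bin
  ab1 <- relative_abundance(data.frame(read_id = "r", contig_id = "c1"),
                            c(c1 = 1L))
  expect_equal(unname(ab1["bin_1"]), 1)
})
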