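test_that("genome generation is deterministic, length-exact and GC-calibrated", {
  spec <- genome_spec("g", 10000, 0.5, 3, seed = 1)
  g1 <- generate_genome(spec)
  expect_identical(g1, generate_genome(spec))
  expect_equal(nchar(g1), 10000)
  expect_true(grepl("^[ACGT]+$", g1))

  g40 <- generate_genome(genome_spec("g", 100000, 0.40, 3, seed = 2))
  gc <- amdscope:::gc_fraction(g40)
  expect_true(abs(gc - 0.40) <= 0.02)

  # order-0 chains calibrate too
  g0 <- generate_genome(genome_spec("g", 50000, 0.65, 0, seed = 3))
  expect_true(abs(amdscope:::gc_fraction(g0) - 0.65) <= 0.02)
})

test_that("invalid genome specs are rejected", {
  expect_error(genome_spec("g", 5000, 0.5), "length")
  expect_error(genome_spec("g", 10000, 0.1), "gc")
  expect_error(genome_spec("g", 10000, 0.9), "gc")
})

test_that("community construction stores abundances, genes and weights consistently", {
  truth <- fx_small_truth()
  expect_equal(sum(truth$abundances), 1, tolerance = 1e-12)
  expect_equal(nrow(truth$genes), 3 * 12)
  # gene intervals lie within genomes and do not overlap
  for (g in names(truth$genomes)) {
    gg <- truth$genes[truth$genes$genome == g, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start >= 1 & gg$end <= nchar(truth$genomes[[g]])))
    expect_true(all(diff(gg$start) > (gg$end - gg$start)[-nrow(gg)]))
  }
  expect_true(all(truth$genes$weight >= 0))
  # determinism of gene coordinates
  truth2 <- generate_community(truth$specs, truth$abundances,
                               genes_per_genome = 12, seed = 9)
  expect_identical(truth$genes, truth2$genes)
  expect_error(
    generate_community(truth$specs, c(0.5, 0.2, 0.2), genes_per_genome = 5),
    "sum to 1")
})

test_that("DNA read pairs come from the right places at the right rates", {
  truth <- fx_small_truth()
  rs <- simulate_dna_reads(truth, 4000, error_rate = 0, seed = 3)
  expect_equal(nrow(rs), 4000)
  expect_true(all(nchar(rs$mate1) == 101))
  expect_true(all(nchar(rs$mate2) == 101))
  # error-free mates are exact substrings (mate2 reverse-complemented)
  idx <- sample.int(4000, 50)
  for (i in idx) {
    genome <- truth$genomes[[rs$origin[i]]]
    expect_identical(rs$mate1[i],
                     substr(genome, rs$start[i], rs$start[i] + 100))
    far <- rs$start[i] + rs$insert[i] - 1
    expect_identical(rs$mate2[i],
                     amdscope:::revcomp(substr(genome, far - 100, far)))
  }
  # origin fractions follow abundance x length (equal lengths here):
  # 3-sigma binomial bound for p = 0.9 at n = 4000 is ~0.0142
  expect_true(abs(mean(rs$origin == "dom") - 0.90) < 0.015)
  # determinism
  rs2 <- simulate_dna_reads(truth, 4000, error_rate = 0, seed = 3)
  expect_identical(rs, rs2)
  expect_error(simulate_dna_reads(truth, 10, read_len = 600,
                                  insert_mean = 500), "insert_mean")
})

test_that("substitution errors hit at roughly the requested rate", {
  truth <- fx_small_truth()
  rs0 <- simulate_dna_reads(truth, 500, error_rate = 0, seed = 4)
  rs1 <- simulate_dna_reads(truth, 500, error_rate = 0.01, seed = 4)
  diffs <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    rs0$mate1, rs1$mate1)
  rate <- sum(diffs) / (500 * 101)
  expect_true(abs(rate - 0.01) < 0.004)
})

test_that("cDNA reads follow gene expression weights", {
  truth <- fx_small_truth()
  probs <- attr(simulate_cdna_reads(truth, 0, seed = 5), "gene_probs")
  expect_equal(sum(probs$prob), 1, tolerance = 1e-12)
  expect_equal(nrow(simulate_cdna_reads(truth, 0, seed = 5)), 0)

  # single positive-weight gene takes every read
  t1 <- truth
  t1$genes$weight <- 0
  t1$genes$weight[5] <- 1
  rs <- simulate_cdna_reads(t1, 200, seed = 6)
  expect_true(all(rs$gene_id == t1$genes$gene_id[5]))
  t1$genes$weight <- 0
  expect_error(simulate_cdna_reads(t1, 10, seed = 1), "zero")

  # two equal-length genes at weights 3:1 -> read counts 3:1 within 3 sigma
  t2 <- truth
  t2$genes$weight <- 0
  g1 <- which(t2$genes$genome == "dom")[1]
  g2 <- which(t2$genes$genome == "dom")[2]
  len <- t2$genes$end[g1] - t2$genes$start[g1]
  t2$genes$end[g2] <- t2$genes$start[g2] + len
  t2$genes$weight[g1] <- 3
  t2$genes$weight[g2] <- 1
  rs <- simulate_cdna_reads(t2, 10000, seed = 7)
  n1 <- sum(rs$gene_id == t2$genes$gene_id[g1])
  p_hat <- n1 / 10000
  expect_true(abs(p_hat - 0.75) < 3 * sqrt(0.75 * 0.25 / 10000))
})

test_that("genome fragmentation yields exact substrings with abundance-scaled coverage", {
  truth <- fx_small_truth()
  ct <- fragment_genomes(truth, 5000, coverage_noise_sd = 0, depth = 100,
                         seed = 8)
  expect_s3_class(ct, "contig_set")
  expect_equal(sum(ct$origin == "dom"), 6)  # 30 kb / 5 kb
  for (i in seq_len(nrow(ct)))
    expect_identical(ct$sequence[i],
                     substr(truth$genomes[[ct$origin[i]]], ct$start[i],
                            ct$start[i] + ct$length[i] - 1))
  # zero noise -> within-genome coverage constant, proportional to abundance
  cov <- tapply(ct$coverage, ct$origin, unique)
  expect_equal(length(unlist(cov)), 3)
  expect_equal(as.numeric(unlist(cov[names(truth$abundances)])),
               as.numeric(truth$abundances * 100))
})

test_that("genomes from different seeds have separable TNF signatures", {
  truth <- fx_small_truth()
  frags <- fragment_genomes(truth, 5000, seed = 10)
  pr <- tnf_profiles(frags, 3000)
  org <- frags$origin[match(rownames(pr), frags$contig_id)]
  D <- as.matrix(dist(pr))
  same <- outer(org, org, "==")
  ut <- upper.tri(D)
  expect_gt(mean(D[!same & ut]), mean(D[same & ut]))
})

test_that("read sets and truth round-trip through FASTQ/FASTA/TSV files", {
  truth <- fx_small_truth()
  dir <- withr::local_tempdir()
  rs <- simulate_dna_reads(truth, 100, seed = 11)
  files <- write_fastq(rs, file.path(dir, "dna"))
  back <- read_fastq_pairs(file.path(dir, "dna_1.fastq"),
                           file.path(dir, "dna_2.fastq"))
  expect_equal(back$mate1, rs$mate1)
  expect_equal(back$mate2, rs$mate2)
  # identical seed -> byte-identical FASTQ
  rs2 <- simulate_dna_reads(truth, 100, seed = 11)
  write_fastq(rs2, file.path(dir, "dnab"))
  expect_identical(readLines(file.path(dir, "dna_1.fastq")),
                   readLines(file.path(dir, "dnab_1.fastq")))
  write_truth(truth, file.path(dir, "truth"))
  genomes <- read_fasta(file.path(dir, "truth", "genomes.fasta"))
  expect_identical(unname(genomes[names(truth$genomes)]),
                   unname(truth$genomes))
})
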