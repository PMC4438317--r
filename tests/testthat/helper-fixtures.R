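# Session-level fixture cache: expensive synthetic data sets are built once
# and shared across test files.
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# small 3-genome community for fast unit tests
fx_small_truth <- function() get_fixture("small_truth", function() {
  specs <- list(genome_spec("dom", 30000, 0.42, 3, 31),
                genome_spec("r1", 30000, 0.58, 3, 32),
                genome_spec("r2", 30000, 0.66, 3, 33))
  generate_community(specs, c(0.90, 0.06, 0.04), genes_per_genome = 12,
                     seed = 9)
})

# the standard 5-genome binning fixture: order-3 genomes with GC contents
# spanning 0.36-0.67, >= 40 contigs each of 5-20 kb, dominant-plus-rare
# abundances
fx_bin_truth <- function() get_fixture("bin_truth", function() {
  gcs <- seq(0.36, 0.67, length.out = 5)
  specs <- lapply(1:5, function(i)
    genome_spec(paste0("g", i), 550000, gcs[i], 3, 50 + i))
  generate_community(specs, c(0.91, 0.03, 0.03, 0.02, 0.01),
                     genes_per_genome = 10, seed = 8)
})

fx_bin_contigs <- function() get_fixture("bin_contigs", function()
  fragment_genomes(fx_bin_truth(), c(5000, 20000), seed = 9))

fx_bin_profiles <- function() get_fixture("bin_profiles", function()
  tnf_profiles(fx_bin_contigs(), 3000))

# expression parameter-recovery fixture: 5 equal-abundance genomes x 50
# genes, 100k cDNA reads and 100k DNA pairs
fx_expr <- function() get_fixture("expr", function() {
  specs <- lapply(1:5, function(i)
    genome_spec(paste0("e", i), 100000, 0.40 + 0.06 * (i - 1), 3, 70 + i))
  truth <- generate_community(specs, rep(0.2, 5), genes_per_genome = 50,
                              seed = 12)
  dna <- simulate_dna_reads(truth, 100000, seed = 13)
  cdna <- simulate_cdna_reads(truth, 100000, seed = 14)
  sidx <- amdscope:::build_seed_index(truth$genomes, 31)
  dmap <- map_reads_to_features(dna, truth$genomes, truth$genes, index = sidx)
  cmap <- map_reads_to_features(cdna, truth$genomes, truth$genes,
                                index = sidx)
  list(truth = truth, dna_map = dmap, cdna_map = cmap)
})

# uniform-expression null: identical expression weights, so transcription
# is proportional to gene dosage and RTA should be ~1 everywhere
fx_null <- function() get_fixture("null", function() {
  specs <- lapply(1:5, function(i)
    genome_spec(paste0("n", i), 100000, 0.40 + 0.06 * (i - 1), 3, 80 + i))
  truth <- generate_community(specs, rep(0.2, 5), genes_per_genome = 50,
                              seed = 15, expr_sdlog = 0)
  dna <- simulate_dna_reads(truth, 100000, seed = 16)
  cdna <- simulate_cdna_reads(truth, 100000, seed = 17)
  sidx <- amdscope:::build_seed_index(truth$genomes, 31)
  list(truth = truth,
       dna_map = map_reads_to_features(dna, truth$genomes, truth$genes,
                                       index = sidx),
       cdna_map = map_reads_to_features(cdna, truth$genomes, truth$genes,
                                        index = sidx))
})

# 10k reads (5k pairs) with a few shortened mates, plus their k-mer table:
# shared by the exact partition oracle checks
fx_partition <- function() get_fixture("partition", function() {
  reads <- simulate_dna_reads(fx_small_truth(), 5000, seed = 21)
  reads$mate1[101:110] <- substr(reads$mate1[101:110], 1, 50)
  reads$mate2[101:105] <- substr(reads$mate2[101:105], 1, 62)
  tab <- count_kmers(reads, 31)
  list(reads = reads, table = tab)
})
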