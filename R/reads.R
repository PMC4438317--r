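new_read_set <- function(df, read_len) {
  structure(df, class = c("read_set", "data.frame"), read_len = read_len)
}

# Apply i.i.d. substitution errors at `rate` per base. Only reads that drew
# at least one error are touched, so the common error_rate = 0 path is free.
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nmut <- rbinom(length(seqs), lens, rate)
  hit <- which(nmut > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nmut[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate paired-end metagenomic (DNA) reads
#'
#' Draws read pairs from the community genomes with probability proportional
#' to abundance times genome length (i.e., uniform coverage within a genome,
#' depth proportional to abundance). Each pair is a forward mate and the
#' reverse-complemented far end of an insert whose size is normal
#' (`insert_mean`, `insert_sd`), truncated to fit the genome. Substitution
#' errors are i.i.d. per base. The true origin genome and position of every
#' pair is recorded for truth-based evaluation.
#'
#' @param truth a [generate_community()] object.
#' @param n_pairs number of read pairs (>= 1).
#' @param read_len read length in bp (default 101, as for 2 x 101 bp
#'   Illumina libraries).
#' @param insert_mean,insert_sd insert size distribution in bp.
#' @param error_rate per-base substitution rate, in \[0, 0.1\].
#' @param seed integer seed.
#' @return A `read_set` data.frame with columns read_id, mate1, mate2,
#'   origin, start (1-based position of mate1 on the forward strand),
#'   insert.
#' @export
simulate_dna_reads <- function(truth, n_pairs, read_len = 101L,
                               insert_mean = 500, insert_sd = 50,
                               error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  assert_that(n_pairs >= 1, "n_pairs must be >= 1")
  assert_that(error_rate >= 0 && error_rate <= 0.1,
              "error_rate must lie in [0, 0.1]")
  assert_that(read_len <= insert_mean,
              "read_len (%d) must not exceed insert_mean (%s)",
              read_len, insert_mean)
  lens <- nchar(truth$genomes)
  prob <- truth$abundances * lens
  with_seed(seed, {
    gi <- sample.int(length(lens), n_pairs, replace = TRUE,
                     prob = prob / sum(prob))
    insert <- pmin(pmax(as.integer(round(rnorm(n_pairs, insert_mean,
                                               insert_sd))),
                        read_len), lens[gi])
    start <- as.integer(floor(runif(n_pairs) * (lens[gi] - insert + 1))) + 1L
    mate1 <- substring(truth$genomes[gi], start, start + read_len - 1L)
    far_end <- start + insert - 1L
    mate2 <- revcomp(substring(truth$genomes[gi], far_end - read_len + 1L,
                               far_end))
    mate1 <- mutate_sequences(mate1, error_rate)
    mate2 <- mutate_sequences(mate2, error_rate)
    new_read_set(data.frame(
      read_id = sprintf("dna_%07d", seq_len(n_pairs)),
      mate1 = mate1, mate2 = mate2,
      origin = names(truth$genomes)[gi], start = start, insert = insert,
      stringsAsFactors = FALSE), read_len)
  })
}

#' Simulate metatranscriptomic (cDNA) reads
#'
#' Draws single-end cDNA reads from gene intervals with probability
#' proportional to genome abundance x expression weight x gene length, so
#' the per-gene ground-truth sampling probabilities (returned as attribute
#' `gene_probs`) are known exactly. Read orientation is random.
#'
#' @param truth a [generate_community()] object; every genome must carry at
#'   least one gene with positive expression weight.
#' @param n_reads number of reads (0 gives an empty read set).
#' @param read_len read length in bp; genes shorter than `read_len` are
#'   excluded from sampling.
#' @param error_rate per-base substitution rate.
#' @param seed integer seed.
#' @return A `read_set` data.frame with columns read_id, mate1 (the read
#'   sequence; mate2 is NA), origin, gene_id, start. Attribute `gene_probs`
#'   is a data.frame (gene_id, prob) with probabilities summing to 1.
#' @export
simulate_cdna_reads <- function(truth, n_reads, read_len = 101L,
                                error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  genes <- truth$genes
  assert_that(all(genes$weight >= 0), "expression weights must be >= 0")
  glen <- genes$end - genes$start + 1L
  prob <- truth$abundances[genes$genome] * genes$weight * glen
  prob[glen < read_len] <- 0
  assert_that(sum(prob) > 0, "all expression weights are zero")
  prob <- prob / sum(prob)
  gene_probs <- data.frame(gene_id = genes$gene_id, prob = as.numeric(prob),
                           stringsAsFactors = FALSE)
  if (n_reads == 0L) {
    out <- new_read_set(data.frame(read_id = character(0),
                                   mate1 = character(0), mate2 = character(0),
                                   origin = character(0),
                                   gene_id = character(0),
                                   start = integer(0),
                                   stringsAsFactors = FALSE), read_len)
    attr(out, "gene_probs") <- gene_probs
    return(out)
  }
  with_seed(seed, {
    gi <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = prob)
    span <- glen[gi] - read_len
    start <- genes$start[gi] + as.integer(floor(runif(n_reads) * (span + 1)))
    seqs <- substring(truth$genomes[genes$genome[gi]], start,
                      start + read_len - 1L)
    rev <- runif(n_reads) < 0.5
    seqs[rev] <- revcomp(seqs[rev])
    seqs <- mutate_sequences(seqs, error_rate)
    out <- new_read_set(data.frame(
      read_id = sprintf("cdna_%07d", seq_len(n_reads)),
      mate1 = seqs, mate2 = NA_character_,
      origin = genes$genome[gi], gene_id = genes$gene_id[gi], start = start,
      stringsAsFactors = FALSE), read_len)
    attr(out, "gene_probs") <- gene_probs
    out
  })
}

#' Fragment genomes into contigs with coverage values
#'
#' Cuts each genome into consecutive fragments, standing in for assembly so
#' that binning can be tested against known contig origins. Fragment lengths
#' are drawn uniformly from `fragment_len` when it is a (min, max) pair, or
#' fixed when it is a single number. Each contig carries its origin genome
#' and a coverage value proportional to abundance (total-depth constant
#' `depth`) with multiplicative log-normal noise.
#'
#' @param truth a [generate_community()] object.
#' @param fragment_len single length or c(min, max) range in bp.
#' @param min_len minimum fragment length retained (>= 500); a truncated
#'   terminal fragment below this is dropped.
#' @param depth total-depth constant: a genome at abundance a gets coverage
#'   `a * depth` before noise.
#' @param coverage_noise_sd sdlog of the multiplicative log-normal coverage
#'   noise (0 = exact).
#' @param seed integer seed.
#' @return A [contig_set()] whose contigs are exact substrings of the source
#'   genomes, with columns origin and start recording the truth.
#' @export
fragment_genomes <- function(truth, fragment_len = 5000L, min_len = 500L,
                             depth = 1000, coverage_noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  assert_that(min_len >= 500, "min_len must be >= 500")
  lo <- as.integer(fragment_len[1L])
  hi <- as.integer(fragment_len[length(fragment_len)])
  assert_that(lo >= min_len, "fragment_len must be >= min_len")
  with_seed(seed, {
    recs <- vector("list", length(truth$genomes))
    for (g in seq_along(truth$genomes)) {
      seq <- truth$genomes[[g]]
      glen <- nchar(seq)
      starts <- integer(0); lens <- integer(0)
      pos <- 1L
      while (pos <= glen) {
        len <- if (lo == hi) lo else
          as.integer(round(runif(1, lo, hi)))
        len <- min(len, glen - pos + 1L)
        starts <- c(starts, pos); lens <- c(lens, len)
        pos <- pos + len
      }
      keep <- lens >= min_len
      starts <- starts[keep]; lens <- lens[keep]
      n <- length(starts)
      cov <- truth$abundances[g] * depth *
        (if (coverage_noise_sd > 0) rlnorm(n, 0, coverage_noise_sd)
         else rep(1, n))
      recs[[g]] <- data.frame(
        contig_id = sprintf("%s_c%04d", names(truth$genomes)[g], seq_len(n)),
        sequence = substring(seq, starts, starts + lens - 1L),
        coverage = as.numeric(cov),
        taxonomy = NA_character_,
        origin = names(truth$genomes)[g],
        start = starts, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
    contig_set(df$contig_id, df$sequence, coverage = df$coverage,
               taxonomy = df$taxonomy, origin = df$origin, start = df$start)
  })
}
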