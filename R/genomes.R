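#' Specify a synthetic genome
#'
#' A genome specification for the synthetic community generator. Sequences
#' are produced by a genome-specific Markov chain whose stationary GC content
#' is calibrated to `gc`, so that genomes generated from different seeds carry
#' distinguishable tetranucleotide signatures -- the property that
#' composition-based binning exploits. The default Markov order of 3 makes
#' 4-mer usage genome-specific.
#'
#' @param name genome label.
#' @param length genome length in bases (>= 10000).
#' @param gc target GC fraction, in \[0.2, 0.8\]. Real draft genomes from
#'   acid-mine-drainage communities span roughly 36--67% GC.
#' @param markov_order order of the generating Markov chain (0--5).
#' @param seed integer seed; the same spec always yields the same sequence.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(name, length, gc, markov_order = 3L, seed = 1L) {
  assert_that(is.numeric(length) && length >= 10000,
              "genome length must be >= 10000 bases, got %s", length)
  assert_that(is.numeric(gc) && gc >= 0.2 && gc <= 0.8,
              "gc must lie in [0.2, 0.8], got %s", gc)
  assert_that(markov_order >= 0 && markov_order <= 5,
              "markov_order must be in 0..5")
  structure(list(name = as.character(name), length = as.integer(length),
                 gc = as.numeric(gc), markov_order = as.integer(markov_order),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Stationary base frequencies of an order-m chain given per-context
# transition probabilities P (4^m x 4).
stationary_base_freq <- function(P) {
  m <- as.integer(round(log(nrow(P), 4)))
  if (m == 0L) return(as.numeric(P[1L, ]))
  nctx <- nrow(P)
  pi <- rep(1 / nctx, nctx)
  # context c -> context ((c-1) mod 4^(m-1)) * 4 + b
  nxt <- outer(((seq_len(nctx) - 1L) %% 4L^(m - 1L)) * 4L, 1:4, `+`)
  for (iter in 1:400) {
    newpi <- numeric(nctx)
    flow <- pi * P
    for (b in 1:4) {
      idx <- nxt[, b]
      newpi[sort(unique(idx))] <- newpi[sort(unique(idx))] +
        as.numeric(rowsum(flow[, b], idx))
    }
    if (sum(abs(newpi - pi)) < 1e-12) { pi <- newpi; break }
    pi <- newpi
  }
  base <- as.numeric(pi %*% P)
  base / sum(base)
}

# Build the transition matrix: random per-context weights tilted so the
# stationary GC equals the target exactly.
markov_transitions <- function(gc, m, seed) {
  nctx <- 4L^m
  w <- with_seed(seed, matrix(runif(nctx * 4L, 0.5, 1.5), nrow = nctx))
  base_bias <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  build <- function(t) {
    tilt <- c(1, exp(t), exp(t), 1)
    P <- sweep(w, 2L, base_bias * tilt, `*`)
    P / rowSums(P)
  }
  gc_of <- function(t) {
    f <- stationary_base_freq(build(t))
    f[2] + f[3] - gc
  }
  t_star <- uniroot(gc_of, c(-4, 4), tol = 1e-10)$root
  build(t_star)
}

#' Generate a synthetic genome sequence
#'
#' Simulates a DNA sequence from the order-`markov_order` Markov chain defined
#' by the spec. The chain's stationary GC content is calibrated to `spec$gc`
#' by solving for a GC tilt of the seeded random transition weights, so the
#' realized GC is within sampling noise of the target. Identical specs yield
#' byte-identical sequences.
#'
#' @param spec a [genome_spec()].
#' @return A single character string of length `spec$length` over A/C/G/T.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  m <- spec$markov_order
  P <- markov_transitions(spec$gc, m, spec$seed)
  cp <- t(apply(P, 1L, cumsum))
  # flat cumulative-probability vector indexed by (ctx-1)*4 + b
  cpv <- as.numeric(t(cp))
  burn <- if (m > 0L) 200L else 0L
  n <- spec$length + burn
  with_seed(spec$seed + 1L, {
    us <- runif(n)
    out <- integer(n)
    if (m == 0L) {
      out <- 1L + (us > cpv[1L]) + (us > cpv[2L]) + (us > cpv[3L])
    } else {
      ctx <- 1L
      modctx <- 4L^(m - 1L)
      for (i in seq_len(n)) {
        off <- (ctx - 1L) * 4L
        u <- us[i]
        b <- 1L + (u > cpv[off + 1L]) + (u > cpv[off + 2L]) + (u > cpv[off + 3L])
        out[i] <- b
        ctx <- ((ctx - 1L) %% modctx) * 4L + b
      }
    }
    paste(BASES[out[(burn + 1L):n]], collapse = "")
  })
}

#' Generate a synthetic community with known ground truth
#'
#' Builds genomes, places non-overlapping gene models on each, and draws
#' per-gene expression weights, producing the ground-truth object every
#' downstream stage is evaluated against. The default abundance structure of
#' interest is one dominant taxon (>90% relative abundance) plus several rare
#' taxa (<1%), as found in low-diversity acid-mine-drainage communities.
#'
#' Expression weights are i.i.d. log-normal (default meanlog 0, sdlog 1),
#' giving the right-skewed transcript pools under which IQR-based outlier
#' detection is meaningful. KO labels are drawn per genome without replacement
#' from a shared pool, so orthologs can be shared across genomes.
#'
#' @param specs list of [genome_spec()] objects.
#' @param abundances numeric vector of relative abundances summing to 1.
#' @param genes_per_genome number of gene models placed on each genome.
#' @param seed integer seed for gene placement and expression weights.
#' @param gene_len_range integer range (min, max) of gene lengths in bp.
#' @param ko_pool optional character vector of KO identifiers to draw from;
#'   defaults to a pool of 80% of the total gene count so some KOs are shared.
#' @param n_categories number of functional categories ("pathways") that KO
#'   identifiers are deterministically assigned to.
#' @param expr_meanlog,expr_sdlog log-normal expression weight parameters.
#' @return An object of class `community_truth`: a list with `genomes` (named
#'   character vector), `specs`, `abundances`, `genes` (data.frame with
#'   genome, gene_id, start, end, strand, ko, category, weight; 1-based
#'   inclusive coordinates) and `params`.
#' @export
generate_community <- function(specs, abundances, genes_per_genome = 20L,
                               seed = 1L, gene_len_range = c(500L, 1500L),
                               ko_pool = NULL, n_categories = 5L,
                               expr_meanlog = 0, expr_sdlog = 1) {
  assert_that(length(specs) == length(abundances),
              "specs and abundances must have equal length")
  assert_that(abs(sum(abundances) - 1) <= 1e-9,
              "abundances must sum to 1 (got %.6f)", sum(abundances))
  assert_that(all(abundances > 0), "abundances must be positive")
  names(abundances) <- vapply(specs, `[[`, "", "name")
  genomes <- vapply(specs, generate_genome, "")
  names(genomes) <- names(abundances)
  n_total <- genes_per_genome * length(specs)
  if (is.null(ko_pool))
    ko_pool <- sprintf("KO%05d", seq_len(max(genes_per_genome,
                                             ceiling(n_total * 0.8))))
  category_of <- sprintf("path%02d",
                         (seq_along(ko_pool) - 1L) %% n_categories + 1L)
  names(category_of) <- ko_pool

  genes <- with_seed(seed, {
    out <- vector("list", length(specs))
    for (gi in seq_along(specs)) {
      glen <- nchar(genomes[[gi]])
      lens <- as.integer(round(runif(genes_per_genome,
                                     gene_len_range[1], gene_len_range[2])))
      gaps <- as.integer(round(runif(genes_per_genome, 50, 400)))
      starts <- cumsum(c(1L + gaps[1L], head(lens, -1L) + gaps[-1L]))
      ends <- starts + lens - 1L
      if (ends[genes_per_genome] > glen)
        stopf("genome %s (%d bp) too short for %d genes of %d-%d bp",
              names(genomes)[gi], glen, genes_per_genome,
              gene_len_range[1], gene_len_range[2])
      kos <- sample(ko_pool, genes_per_genome, replace = FALSE)
      out[[gi]] <- data.frame(
        genome = names(genomes)[gi],
        gene_id = sprintf("%s_g%03d", names(genomes)[gi],
                          seq_len(genes_per_genome)),
        start = starts, end = ends,
        strand = sample(c("+", "-"), genes_per_genome, replace = TRUE),
        ko = kos, category = unname(category_of[kos]),
        weight = rlnorm(genes_per_genome, expr_meanlog, expr_sdlog),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(genes) <- NULL
  structure(list(genomes = genomes, specs = specs, abundances = abundances,
                 genes = genes,
                 params = list(seed = seed, genes_per_genome = genes_per_genome,
                               gene_len_range = gene_len_range,
                               expr_meanlog = expr_meanlog,
                               expr_sdlog = expr_sdlog,
                               n_categories = n_categories)),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf("community_truth: %d genomes, %d genes\n",
              length(x$genomes), nrow(x$genes)))
  df <- data.frame(genome = names(x$genomes),
                   length = nchar(x$genomes),
                   gc = round(vapply(x$genomes, gc_fraction, 0), 3),
                   abundance = as.numeric(x$abundances))
  rownames(df) <- NULL
  print(df, ...)
  invisible(x)
}
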