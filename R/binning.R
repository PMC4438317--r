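# The 136 canonical tetranucleotide classes: each 4-mer pooled with its
# reverse complement (16 palindromes + 120 pairs).
canonical_tetramers <- function() {
  all4 <- Biostrings::mkAllStrings(BASES, 4L)
  sort(unique(pmin(all4, revcomp(all4))))
}

#' Tetranucleotide frequency profile of a contig
#'
#' Counts all length-4 ACGT windows of the sequence, pools each 4-mer with
#' its reverse complement into 136 canonical classes (so a contig and its
#' reverse complement share a profile), and normalizes to frequencies. TNF
#' is a compositional signature that separates contigs by genome of origin;
#' contigs shorter than `min_len` (default 3000 bp, the usual binning
#' cutoff) carry too noisy a signature and are rejected.
#'
#' @param sequence a contig sequence.
#' @param min_len minimum contig length in bp.
#' @return Named numeric vector of 136 canonical tetranucleotide
#'   frequencies summing to 1.
#' @export
tnf_profile <- function(sequence, min_len = 3000L) {
  if (nchar(sequence) < min_len)
    stop(structure(class = c("amdscope_skip", "error", "condition"),
                   list(message = sprintf(
                     "contig (%d bp) below TNF length cutoff %d",
                     nchar(sequence), min_len), call = NULL)))
  tnf_profile_matrix(sequence)[1L, ]
}

# TNF matrix for many sequences at once (no length filtering).
tnf_profile_matrix <- function(sequences) {
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = 4L)
  classes <- canonical_tetramers()
  canon <- pmin(colnames(counts), revcomp(colnames(counts)))
  pooled <- t(rowsum(t(counts), canon))
  pooled <- pooled[, classes, drop = FALSE]
  tot <- rowSums(pooled)
  tot[tot == 0] <- 1
  pooled / tot
}

#' TNF profiles for a contig set
#'
#' @param contigs a [contig_set()].
#' @param min_len minimum contig length; shorter contigs are skipped and
#'   listed in attribute `skipped`.
#' @return Numeric matrix (contigs x 136 canonical classes) with contig ids
#'   as row names.
#' @export
tnf_profiles <- function(contigs, min_len = 3000L) {
  stopifnot(inherits(contigs, "contig_set"))
  keep <- contigs$length >= min_len
  m <- tnf_profile_matrix(contigs$sequence[keep])
  rownames(m) <- contigs$contig_id[keep]
  attr(m, "skipped") <- contigs$contig_id[!keep]
  m
}

#' Cluster contigs by TNF with Ward linkage
#'
#' Hierarchical agglomerative clustering of TNF profiles using Euclidean
#' distance and the Ward criterion, cut at `n_bins` clusters. Profiles are
#' used as raw frequencies (no standardization).
#'
#' @param profiles matrix from [tnf_profiles()].
#' @param n_bins number of bins to cut the tree at.
#' @return An object of class `bin_assignment`: list(bins = named integer
#'   vector contig -> bin id (dense from 1), tree = the hclust object).
#' @export
cluster_contigs <- function(profiles, n_bins) {
  assert_that(n_bins >= 1, "n_bins must be >= 1")
  assert_that(n_bins <= nrow(profiles),
              "n_bins (%d) exceeds number of profiles (%d)",
              n_bins, nrow(profiles))
  hc <- hclust(dist(profiles), method = "ward.D2")
  bins <- cutree(hc, k = n_bins)
  names(bins) <- rownames(profiles)
  structure(list(bins = bins, tree = hc), class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("bin_assignment: %d contigs in %d bins (%d unbinned)\n",
              length(x$bins), length(unique(x$bins[!is.na(x$bins)])),
              sum(is.na(x$bins))))
  invisible(x)
}

#' Choose the number of bins
#'
#' Cuts the Ward tree at every k in `k_min:k_max` and picks the k with the
#' highest mean silhouette width. NMDS stress at each dimensionality is
#' reported alongside as an ordination diagnostic (the classical visual
#' criterion), but the silhouette decides.
#'
#' @param profiles matrix from [tnf_profiles()] (>= 3 rows).
#' @param k_min,k_max candidate range, 2 <= k_min < k_max <= n-1.
#' @param nmds_seed seed forwarded to [nmds()] for the stress diagnostics.
#' @return list(k = chosen k, diagnostics = data.frame(k, silhouette,
#'   stress)).
#' @export
select_bin_count <- function(profiles, k_min = 2L, k_max = 10L,
                             nmds_seed = 1L) {
  n <- nrow(profiles)
  assert_that(n >= 3, "need at least 3 profiles")
  k_max <- min(k_max, n - 1L)
  assert_that(k_min >= 2 && k_min < k_max,
              "need 2 <= k_min < k_max <= n-1")
  d <- dist(profiles)
  hc <- hclust(d, method = "ward.D2")
  ks <- k_min:k_max
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, 0)
  stress <- vapply(ks, function(k) {
    if (k >= n - 1L) return(NA_real_)
    nmds(as.matrix(d), dims = k, seed = nmds_seed)$stress
  }, 0)
  diagnostics <- data.frame(k = ks, silhouette = sil, stress = stress)
  list(k = ks[which.max(sil)], diagnostics = diagnostics)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS: iterative majorization with monotone (isotonic)
#' regression on dissimilarity ranks, as implemented by
#' [vegan::monoMDS()], starting from the metric (principal coordinates)
#' configuration so results are reproducible.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal (or a
#'   `dist`).
#' @param dims embedding dimensionality.
#' @param max_iter,tol iteration controls passed to monoMDS.
#' @param seed RNG seed (the start is deterministic; the seed guards any
#'   internal randomness).
#' @return An object of class `ordination_result`: list(points = n x dims
#'   coordinate matrix, stress = Kruskal stress-1 in \[0, 1\]).
#' @export
nmds <- function(d, dims = 2L, max_iter = 500L, tol = 1e-7, seed = 1L) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    assert_that(isSymmetric(unname(d)), "distance matrix must be symmetric")
    assert_that(all(d >= 0), "distances must be non-negative")
    assert_that(all(abs(diag(d)) < 1e-12), "diagonal must be zero")
    d <- stats::as.dist(d)
  }
  fit <- with_seed(seed,
    vegan::monoMDS(d, k = dims, maxit = max_iter, sratmax = 1 - tol))
  structure(list(points = fit$points, stress = fit$stress),
            class = "ordination_result")
}

bin_stats <- function(bins, coverage) {
  stats_by <- split(coverage, bins)
  data.frame(bin = as.integer(names(stats_by)),
             median = vapply(stats_by, median, 0),
             mad = vapply(stats_by, mad, 0))
}

#' Refine bins by coverage and taxonomy consistency
#'
#' Reproduces, as a deterministic rule, the manual curation step in which
#' contigs with divergent coverage or phylogenetic assignment are moved or
#' removed: a contig whose coverage deviates from its bin's median by more
#' than `mad_factor` x MAD, or whose taxonomy label conflicts with its
#' bin's majority label, is reassigned to the nearest other bin (by
#' Euclidean distance to the bin's mean TNF) whose coverage band and
#' majority taxonomy it is compatible with, or marked unbinned (NA) when
#' none qualifies. All decisions use the statistics of the input
#' assignment, so the result is order-independent.
#'
#' @param assignment a [cluster_contigs()] result.
#' @param profiles TNF matrix covering the binned contigs.
#' @param coverage named numeric coverage per binned contig.
#' @param taxonomy optional named taxonomy label per contig (NA = unknown).
#' @param mad_factor coverage divergence multiplier (default 3).
#' @return A `bin_assignment` with updated `bins` (NA = unbinned) and a
#'   `moves` data.frame recording each reassignment and its reason.
#' @export
refine_bins <- function(assignment, profiles, coverage, taxonomy = NULL,
                        mad_factor = 3) {
  stopifnot(inherits(assignment, "bin_assignment"))
  bins <- assignment$bins
  ids <- names(bins)
  assert_that(all(ids %in% names(coverage)),
              "coverage needed for every binned contig")
  cov <- coverage[ids]
  tax <- if (is.null(taxonomy)) setNames(rep(NA_character_, length(ids)), ids)
         else taxonomy[ids]
  st <- bin_stats(bins, cov)
  majority <- vapply(split(tax, bins), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    tb <- sort(table(v), decreasing = TRUE)
    names(tb)[1L]
  }, "")
  centroids <- rowsum(profiles[ids, , drop = FALSE], bins)
  centroids <- centroids / as.numeric(table(bins))
  cov_ok <- function(b, x) {
    row <- st[st$bin == b, ]
    tol <- mad_factor * row$mad
    abs(x - row$median) <= max(tol, 1e-9)
  }
  tax_ok <- function(b, label)
    is.na(label) || is.na(majority[as.character(b)]) ||
      label == majority[as.character(b)]
  moves <- list()
  newbins <- bins
  for (i in seq_along(ids)) {
    b <- bins[i]
    reason <- NULL
    if (!cov_ok(b, cov[i])) reason <- "coverage"
    if (!tax_ok(b, tax[i])) reason <- c(reason, "taxonomy")
    if (is.null(reason)) next
    cands <- setdiff(st$bin, b)
    cands <- cands[vapply(cands, function(bb)
      cov_ok(bb, cov[i]) && tax_ok(bb, tax[i]), TRUE)]
    if (length(cands) == 0L) {
      newbins[i] <- NA_integer_
      dest <- NA_integer_
    } else {
      dd <- vapply(cands, function(bb)
        sqrt(sum((profiles[ids[i], ] - centroids[as.character(bb), ])^2)), 0)
      dest <- cands[which.min(dd)]
      newbins[i] <- dest
    }
    moves[[length(moves) + 1L]] <- data.frame(
      contig_id = ids[i], from = b, to = dest,
      reason = paste(reason, collapse = "+"), stringsAsFactors = FALSE)
  }
  out <- structure(list(bins = newbins, tree = assignment$tree),
                   class = "bin_assignment")
  out$moves <- if (length(moves)) do.call(rbind, moves)
    else data.frame(contig_id = character(0), from = integer(0),
                    to = integer(0), reason = character(0))
  out
}

#' Flag contigs containing large internal repeats
#'
#' A simplified chimera screen: each contig is compared against itself by
#' sliding `span`-length windows (non-overlapping by default) and searching
#' for a second, non-overlapping occurrence of the window at `identity` or
#' better on either strand. Contigs assembled through a long repeat are the
#' typical source of chimeric joins.
#'
#' @param contigs a [contig_set()].
#' @param span minimum duplicated block length in bp (default 500).
#' @param identity minimum fractional identity of the duplication.
#' @param step window step in bp; defaults to `span` (non-overlapping
#'   windows), which bounds detection granularity: duplications shorter
#'   than about `2 * span - step` can be missed if no window falls inside
#'   both copies.
#' @return data.frame(contig_id, start1, end1, start2, end2, strand), one
#'   row per flagged contig (first detected repeat).
#' @details Detection is seeded: several exact 31-mers of each window are
#'   located by string search and a candidate second copy is verified by
#'   gapless (substitution-only) identity at the implied offset. At 98%
#'   identity the chance that all seeds of a true copy are mutated is
#'   negligible; indel-shifted copies are outside the detection model.
#' @export
flag_chimeras <- function(contigs, span = 500L, identity = 0.98,
                          step = span) {
  stopifnot(inherits(contigs, "contig_set"))
  seed_len <- 31L
  out <- list()
  hamming_id <- function(a, b)
    mean(strsplit(a, "", fixed = TRUE)[[1L]] ==
         strsplit(b, "", fixed = TRUE)[[1L]])
  for (i in seq_len(nrow(contigs))) {
    L <- contigs$length[i]
    if (L < 2L * span) next
    cseq <- contigs$sequence[i]
    # prescreen: a >= span repeat at >= identity implies a duplicated
    # canonical seed k-mer somewhere in the contig; random contigs have
    # none and are skipped outright
    if (anyDuplicated(canonicalize(seq_windows(cseq, seed_len))) == 0L)
      next
    starts <- seq(1L, L - span + 1L, by = step)
    found <- NULL
    for (s in starts) {
      w <- substr(cseq, s, s + span - 1L)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") w else revcomp(w)
        offs <- seq(1L, span - seed_len + 1L, by = 47L)
        cand <- integer(0)
        for (o in offs) {
          g <- gregexpr(substr(pat, o, o + seed_len - 1L), cseq,
                        fixed = TRUE)[[1L]]
          if (g[1L] != -1L) cand <- c(cand, as.integer(g) - o + 1L)
        }
        cand <- unique(cand)
        cand <- cand[cand >= 1L & cand + span - 1L <= L]
        if (strand == "+") cand <- cand[abs(cand - s) >= span]
        for (p in cand) {
          if (hamming_id(pat, substr(cseq, p, p + span - 1L)) >= identity) {
            found <- list(s = s, pos = p, strand = strand)
            break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (!is.null(found))
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contigs$contig_id[i],
        start1 = found$s, end1 = found$s + span - 1L,
        start2 = found$pos, end2 = found$pos + span - 1L,
        strand = found$strand, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(contig_id = character(0), start1 = integer(0),
                  end1 = integer(0), start2 = integer(0), end2 = integer(0),
                  strand = character(0))
}

#' Estimate bin completeness from core genes
#'
#' Completeness is the fraction of a reference core-gene set observed in
#' the bin: |distinct core genes present| / |core set|. Duplicates count
#' once.
#'
#' @param bin_genes character vector of gene (or KO) identifiers annotated
#'   in the bin.
#' @param core_gene_set non-empty character vector of core gene
#'   identifiers.
#' @return Fraction in \[0, 1\].
#' @export
estimate_completeness <- function(bin_genes, core_gene_set) {
  assert_that(length(core_gene_set) > 0, "core gene set must be non-empty")
  core <- unique(core_gene_set)
  length(intersect(unique(bin_genes), core)) / length(core)
}

#' Per-bin relative abundance from read mapping
#'
#' The read-mapping abundance of a bin is the number of quality reads
#' mapped to its contigs divided by the total number of quality reads.
#' Reads mapping to contigs that carry no bin (unbinned by refinement, or
#' below the binning length cutoff) are reported under "unbinned" and
#' reads mapping nowhere under "unmapped", so the fractions sum to 1.
#'
#' @param mapping data.frame(read_id, contig_id) with NA contig_id for
#'   unmapped reads; each read assigned to at most one contig.
#' @param assignment a `bin_assignment` (or a named vector contig -> bin).
#' @return Named numeric vector of per-bin fractions (names "bin_<i>") plus
#'   "unbinned" and "unmapped" entries; sums to 1.
#' @export
relative_abundance <- function(mapping, assignment) {
  bins <- if (inherits(assignment, "bin_assignment")) assignment$bins
          else assignment
  assert_that(!anyDuplicated(mapping$read_id),
              "each read may be assigned to at most one contig")
  total <- nrow(mapping)
  assert_that(total > 0, "mapping table is empty")
  bin_of_read <- bins[as.character(mapping$contig_id)]
  mapped <- !is.na(mapping$contig_id) & !is.na(bin_of_read)
  tab <- table(bin_of_read[mapped])
  all_bins <- sort(unique(bins[!is.na(bins)]))
  out <- setNames(rep(0, length(all_bins)), paste0("bin_", all_bins))
  out[paste0("bin_", names(tab))] <- as.numeric(tab) / total
  unbinned <- sum(!is.na(mapping$contig_id) & !mapped) / total
  unmapped <- sum(is.na(mapping$contig_id)) / total
  c(out, unbinned = unbinned, unmapped = unmapped)
}

#' Summarize bins
#'
#' Table-style per-bin summary: contig count, total bases, mean GC, mean
#' coverage and (when a core gene set and per-contig gene annotations are
#' given) completeness.
#'
#' @param assignment a `bin_assignment`.
#' @param contigs the [contig_set()] the assignment refers to.
#' @param contig_genes optional data.frame(contig_id, gene) of annotations.
#' @param core_gene_set optional core gene identifiers for completeness.
#' @return data.frame(bin, n_contigs, total_bases, gc, coverage,
#'   completeness).
#' @export
bin_summary <- function(assignment, contigs, contig_genes = NULL,
                        core_gene_set = NULL) {
  stopifnot(inherits(assignment, "bin_assignment"))
  bins <- assignment$bins
  idx <- match(names(bins), contigs$contig_id)
  assert_that(!anyNA(idx), "assignment refers to contigs absent from the set")
  keep <- !is.na(bins)
  gc <- gc_fraction(contigs$sequence[idx])
  df <- data.frame(bin = bins[keep], length = contigs$length[idx][keep],
                   gc = gc[keep], coverage = contigs$coverage[idx][keep],
                   contig_id = names(bins)[keep])
  agg <- do.call(rbind, lapply(split(df, df$bin), function(d) {
    comp <- NA_real_
    if (!is.null(contig_genes) && !is.null(core_gene_set))
      comp <- estimate_completeness(
        contig_genes$gene[contig_genes$contig_id %in% d$contig_id],
        core_gene_set)
    data.frame(bin = d$bin[1L], n_contigs = nrow(d),
               total_bases = sum(d$length),
               gc = sum(d$gc * d$length) / sum(d$length),
               coverage = mean(d$coverage), completeness = comp)
  }))
  rownames(agg) <- NULL
  agg[order(agg$bin), ]
}
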