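#' Build an expression table
#'
#' The feature x genome count container for the transcriptional statistics:
#' one row per (feature, genome) with DNA and cDNA read counts, plus
#' per-genome totals. Features may be genes, KOs or COGs; with
#' `level = "KO"` gene counts are aggregated by their KO label.
#'
#' Two totals are kept per genome and molecule: reads mapped to any
#' feature (`*_gene_total`, the default denominator for relative
#' abundances) and all mapped reads including intergenic (`*_all_total`).
#'
#' @param dna_map,cdna_map results of [map_reads_to_features()] for the DNA
#'   and cDNA read sets.
#' @param gene_models data.frame(genome, gene_id, ko) linking genes to KO
#'   labels (used for `level = "KO"`).
#' @param level "gene" or "KO".
#' @return An object of class `expression_table`: list(counts = data.frame
#'   (feature, level, genome, dna_count, cdna_count), totals = data.frame
#'   (genome, dna_gene_total, dna_all_total, cdna_gene_total,
#'   cdna_all_total), level).
#' @export
expression_table <- function(dna_map, cdna_map, gene_models,
                             level = c("gene", "KO")) {
  level <- match.arg(level)
  per_gene <- function(m) {
    dt <- as.data.table(m$counts)[!is.na(gene_id)]
    setnames(dt, "gene_id", "feature")
    dt
  }
  dna <- per_gene(dna_map); cdna <- per_gene(cdna_map)
  if (level == "KO") {
    gm <- as.data.table(gene_models)[, c("gene_id", "ko"), with = FALSE]
    relabel <- function(dt) {
      dt <- gm[dt, on = c(gene_id = "feature")]
      dt[, list(count = sum(count)), by = c("genome", "ko")][
        , list(genome = genome, feature = ko, count = count)]
    }
    dna <- relabel(dna); cdna <- relabel(cdna)
  }
  setnames(dna, "count", "dna_count")
  setnames(cdna, "count", "cdna_count")
  counts <- merge(dna, cdna, by = c("genome", "feature"), all = TRUE)
  counts[is.na(counts)] <- 0L
  totals_of <- function(m, prefix) {
    t <- as.data.table(m$totals)
    setnames(t, c("mapped_reads", "gene_reads"),
             paste0(prefix, c("_all_total", "_gene_total")))
    t
  }
  totals <- merge(totals_of(dna_map, "dna"), totals_of(cdna_map, "cdna"),
                  by = "genome", all = TRUE)
  totals[is.na(totals)] <- 0L
  counts <- as.data.frame(counts)
  counts$level <- level
  new_expression_table(counts[, c("feature", "level", "genome",
                                  "dna_count", "cdna_count")],
                       as.data.frame(totals), level)
}

#' Assemble an expression table from plain count data
#'
#' Entry point for externally produced counts (e.g. a TSV of per-feature
#' read counts): validates and wraps them in the same container
#' [expression_table()] produces.
#'
#' @param counts data.frame(feature, genome, dna_count, cdna_count).
#' @param totals optional data.frame(genome, dna_gene_total, dna_all_total,
#'   cdna_gene_total, cdna_all_total); missing totals default to the
#'   per-genome count sums (with all_total = gene_total).
#' @param level feature level label ("gene", "KO" or "COG").
#' @return An `expression_table`.
#' @export
expression_table_from_counts <- function(counts, totals = NULL,
                                         level = "KO") {
  assert_that(all(c("feature", "genome", "dna_count", "cdna_count") %in%
                  names(counts)), "counts needs feature/genome/dna_count/cdna_count")
  assert_that(all(counts$dna_count >= 0) && all(counts$cdna_count >= 0),
              "counts must be non-negative")
  if (is.null(totals)) {
    dt <- as.data.table(counts)
    totals <- as.data.frame(dt[, list(
      dna_gene_total = sum(dna_count), dna_all_total = sum(dna_count),
      cdna_gene_total = sum(cdna_count), cdna_all_total = sum(cdna_count)),
      by = "genome"])
  }
  counts$level <- level
  new_expression_table(
    as.data.frame(counts)[, c("feature", "level", "genome",
                              "dna_count", "cdna_count")],
    totals, level)
}

new_expression_table <- function(counts, totals, level) {
  bad <- merge(aggregate(cbind(dna = counts$dna_count,
                               cdna = counts$cdna_count),
                         by = list(genome = counts$genome), FUN = sum),
               totals, by = "genome")
  assert_that(all(bad$dna <= bad$dna_all_total + 1e-9) &&
              all(bad$cdna <= bad$cdna_all_total + 1e-9),
              "feature counts exceed genome totals")
  structure(list(counts = counts, totals = totals, level = level),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table (%s level): %d features x %d genomes\n",
              x$level, length(unique(x$counts$feature)),
              length(unique(x$counts$genome))))
  invisible(x)
}

#' Per-feature relative abundances
#'
#' The share of a genome's reads carried by each feature: count divided by
#' the genome total, separately for DNA and cDNA. Genomes with a zero total
#' are excluded (with the reason recorded in attribute `excluded`), the
#' treatment given to taxa with too little associated information.
#'
#' @param table an `expression_table`.
#' @param denominator "gene" (reads mapped to features; default) or "all"
#'   (all mapped reads including intergenic).
#' @return data.frame(feature, genome, dna_count, cdna_count, dna_share,
#'   cdna_share).
#' @export
relative_abundances <- function(table, denominator = c("gene", "all")) {
  stopifnot(inherits(table, "expression_table"))
  denominator <- match.arg(denominator)
  tot <- table$totals
  dna_tot <- setNames(tot[[paste0("dna_", denominator, "_total")]],
                      tot$genome)
  cdna_tot <- setNames(tot[[paste0("cdna_", denominator, "_total")]],
                       tot$genome)
  excluded <- tot$genome[dna_tot[tot$genome] == 0 |
                         cdna_tot[tot$genome] == 0]
  df <- table$counts[!(table$counts$genome %in% excluded), ]
  df$dna_share <- df$dna_count / dna_tot[df$genome]
  df$cdna_share <- df$cdna_count / cdna_tot[df$genome]
  rownames(df) <- NULL
  structure(df, excluded = excluded)
}

#' Relative transcriptional activity (RTA)
#'
#' RTA of feature a in genome b is the ratio of the feature's share of the
#' genome's cDNA reads to its share of the genome's DNA reads:
#' `RTA = cDNA_ab / DNA_ab`. RTA = 1 means transcription proportional to
#' gene dosage. When a feature has cDNA but no DNA reads the ratio is
#' undefined; a pseudocount of 0.5 is then added to both counts and the
#' value flagged (`pseudo = TRUE`). Features with neither kind of read get
#' NA with `undefined_reason = "no_reads"`.
#'
#' @param table an `expression_table`.
#' @param denominator forwarded to [relative_abundances()].
#' @param pseudocount value added to both counts in the zero-DNA case.
#' @return data.frame(feature, genome, dna_count, cdna_count, dna_share,
#'   cdna_share, rta, pseudo, undefined_reason), class `rta_result`.
#' @export
rta <- function(table, denominator = c("gene", "all"), pseudocount = 0.5) {
  stopifnot(inherits(table, "expression_table"))
  denominator <- match.arg(denominator)
  df <- relative_abundances(table, denominator)
  df$pseudo <- df$dna_count == 0 & df$cdna_count > 0
  df$undefined_reason <- ifelse(df$dna_count == 0 & df$cdna_count == 0,
                                "no_reads", NA_character_)
  dna_share <- df$dna_share
  cdna_share <- df$cdna_share
  if (any(df$pseudo)) {
    tot <- table$totals
    dna_tot <- setNames(tot[[paste0("dna_", denominator, "_total")]],
                        tot$genome)
    cdna_tot <- setNames(tot[[paste0("cdna_", denominator, "_total")]],
                         tot$genome)
    i <- df$pseudo
    dna_share[i] <- (df$dna_count[i] + pseudocount) / dna_tot[df$genome[i]]
    cdna_share[i] <- (df$cdna_count[i] + pseudocount) / cdna_tot[df$genome[i]]
  }
  df$rta <- ifelse(is.na(df$undefined_reason) | df$pseudo,
                   cdna_share / dna_share, NA_real_)
  df$rta[!is.na(df$undefined_reason)] <- NA_real_
  rownames(df) <- NULL
  structure(df, class = c("rta_result", "data.frame"),
            excluded = attr(df, "excluded"))
}

#' Detect expression outliers by the IQR rule
#'
#' Within each genome, computes quartiles (linear-interpolation convention,
#' `stats::quantile` type 7) of the cDNA read counts over all features and
#' flags those exceeding the fence. Two readings of the "1.5 x IQR" rule
#' are available: the standard boxplot fence `count > Q3 + factor * IQR`
#' (default) and the literal threshold `count > factor * IQR`.
#'
#' @param table an `expression_table`.
#' @param factor fence multiplier (default 1.5).
#' @param mode "fence" or "literal" (see above).
#' @param min_features genomes with fewer features than this are skipped
#'   with a warning (default 4, the minimum for meaningful quartiles).
#' @return data.frame(feature, genome, cdna_count, outlier), class
#'   `outlier_result`; skipped genomes listed in attribute `skipped`.
#' @export
detect_outliers <- function(table, factor = 1.5,
                            mode = c("fence", "literal"),
                            min_features = 4L) {
  stopifnot(inherits(table, "expression_table"))
  mode <- match.arg(mode)
  df <- table$counts
  out <- lapply(split(df, df$genome), function(d) {
    if (nrow(d) < min_features) {
      warning(sprintf("genome %s skipped: only %d features (< %d)",
                      d$genome[1L], nrow(d), min_features), call. = FALSE)
      return(NULL)
    }
    q <- quantile(d$cdna_count, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    fence <- if (mode == "fence") q[2L] + factor * iqr else factor * iqr
    data.frame(feature = d$feature, genome = d$genome,
               cdna_count = d$cdna_count,
               outlier = d$cdna_count > fence,
               stringsAsFactors = FALSE)
  })
  skipped <- names(out)[vapply(out, is.null, TRUE)]
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature = character(0), genome = character(0),
                      cdna_count = integer(0), outlier = logical(0))
  rownames(res) <- NULL
  structure(res, class = c("outlier_result", "data.frame"), skipped = skipped)
}

#' Indicator value of a feature across genomes
#'
#' The concentration statistic behind indicator-KO calls: for feature a and
#' genome b, `IV(a,b) = 100 * share(a,b) / sum_j share(a,j)` where
#' share(a,b) is the feature's fraction of genome b's total cDNA reads and
#' the sum runs over all g genomes. IV sums to 100 over genomes for every
#' expressed feature; an IV above 50 means the feature's relative
#' expression is concentrated in that single genome.
#'
#' @param table an `expression_table`.
#' @param denominator forwarded to the cDNA share computation.
#' @return data.frame(feature, genome, cdna_share, iv) covering the full
#'   feature x genome grid, class `iv_result`, with attribute `g` = number
#'   of genomes.
#' @export
indicator_value <- function(table, denominator = c("gene", "all")) {
  stopifnot(inherits(table, "expression_table"))
  denominator <- match.arg(denominator)
  tot <- table$totals
  cdna_tot <- setNames(tot[[paste0("cdna_", denominator, "_total")]],
                       tot$genome)
  genomes <- sort(unique(tot$genome[cdna_tot[tot$genome] > 0]))
  features <- sort(unique(table$counts$feature))
  grid <- data.table(feature = rep(features, each = length(genomes)),
                     genome = rep(genomes, length(features)))
  cnt <- as.data.table(table$counts)[, c("feature", "genome", "cdna_count"),
                                     with = FALSE]
  grid <- cnt[grid, on = c("feature", "genome")]
  grid[is.na(grid$cdna_count), "cdna_count"] <- 0L
  set(grid, j = "cdna_share",
      value = grid$cdna_count / cdna_tot[grid$genome])
  totshare <- grid[, list(tot_share = sum(cdna_share)), by = "feature"]
  grid <- totshare[grid, on = "feature"]
  set(grid, j = "iv",
      value = ifelse(grid$tot_share > 0,
                     100 * grid$cdna_share / grid$tot_share, 0))
  res <- as.data.frame(grid[, c("feature", "genome", "cdna_share", "iv"),
                            with = FALSE])
  structure(res, class = c("iv_result", "data.frame"), g = length(genomes))
}

#' Call indicator features
#'
#' A feature is an indicator for a genome when it is an expression outlier
#' there AND its indicator value strictly exceeds `threshold` (IV > 50 by
#' default; exactly 50 does not qualify).
#'
#' @param outliers result of [detect_outliers()].
#' @param iv result of [indicator_value()].
#' @param threshold IV cutoff (strict inequality).
#' @return data.frame(feature, genome, outlier, iv, indicator).
#' @export
identify_indicators <- function(outliers, iv, threshold = 50) {
  df <- merge(as.data.frame(outliers)[, c("feature", "genome", "outlier")],
              as.data.frame(iv)[, c("feature", "genome", "iv")],
              by = c("feature", "genome"), all.y = TRUE)
  df$outlier[is.na(df$outlier)] <- FALSE
  df$indicator <- df$outlier & df$iv > threshold
  df[order(df$feature, df$genome), ]
}

#' Per-category Wilcoxon contrasts of RTA across taxa
#'
#' For every functional category and genome, tests whether the genome's RTA
#' values in that category differ from all other genomes' RTA values in the
#' same category (two-sample Wilcoxon rank-sum; exact null for small
#' tie-free samples, normal approximation with tie correction otherwise,
#' as provided by [stats::wilcox.test()]). A category is flagged as
#' overrepresented in a genome when p < alpha and the genome's median RTA
#' is the higher one. No multiple-testing correction is applied.
#'
#' @param rta_result an [rta()] result.
#' @param categories data.frame(feature, category) mapping features to
#'   pathways/COG categories.
#' @param alpha significance level (default 0.05).
#' @return data.frame(category, genome, n_in, n_out, p, overrepresented,
#'   reason) where reason records degenerate groups (NA p).
#' @export
compare_rta <- function(rta_result, categories, alpha = 0.05) {
  df <- merge(as.data.frame(rta_result)[, c("feature", "genome", "rta")],
              categories, by = "feature")
  df <- df[!is.na(df$rta), ]
  out <- list()
  for (cat in sort(unique(df$category))) {
    d <- df[df$category == cat, ]
    for (g in sort(unique(d$genome))) {
      x <- d$rta[d$genome == g]
      y <- d$rta[d$genome != g]
      if (length(x) < 2L || length(y) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          category = cat, genome = g, n_in = length(x), n_out = length(y),
          p = NA_real_, overrepresented = FALSE,
          reason = "fewer than 2 observations in a group",
          stringsAsFactors = FALSE)
        next
      }
      p <- suppressWarnings(wilcox.test(x, y)$p.value)
      out[[length(out) + 1L]] <- data.frame(
        category = cat, genome = g, n_in = length(x), n_out = length(y),
        p = p, overrepresented = !is.na(p) && p < alpha &&
          median(x) > median(y),
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean RTA per category and genome
#'
#' The activity of a category (metabolism) in a taxon is the mean RTA of
#' all its features there -- the matrix behind z-scored activity profiles.
#'
#' @param rta_result an [rta()] result.
#' @param categories data.frame(feature, category).
#' @return Numeric matrix, categories x genomes.
#' @export
category_rta <- function(rta_result, categories) {
  df <- merge(as.data.frame(rta_result)[, c("feature", "genome", "rta")],
              categories, by = "feature")
  df <- df[!is.na(df$rta), ]
  tab <- tapply(df$rta, list(df$category, df$genome), mean)
  tab[is.na(tab)] <- 0
  tab
}

#' z-score a category x taxon activity matrix
#'
#' Each row (category) is centered and scaled to unit variance across taxa
#' using the population (n-denominator) standard deviation, the convention
#' for normalizing over a fixed, complete set of taxa. Zero-variance rows
#' become all zeros and are listed in attribute `flat_rows`.
#'
#' @param mat numeric matrix, categories x taxa.
#' @return Matrix of the same shape; each non-flat row has mean 0 and
#'   population sd 1.
#' @export
zscore_profile <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  flat <- sd_pop < 1e-12
  z <- (mat - mu) / ifelse(flat, 1, sd_pop)
  z[flat, ] <- 0
  structure(z, flat_rows = rownames(mat)[flat])
}

#' Top expressed features per genome
#'
#' Ranks features by RTA within each genome and returns the top `n`; ties
#' are broken by higher cDNA count, then feature id, so the ranking is
#' deterministic. Genomes with fewer than `n` defined values return all of
#' them with a warning.
#'
#' @param rta_result an [rta()] result.
#' @param n number of features to keep per genome (default 10).
#' @return data.frame(genome, rank, feature, rta, cdna_count).
#' @export
top_expressed <- function(rta_result, n = 10L) {
  df <- as.data.frame(rta_result)
  df <- df[!is.na(df$rta), ]
  out <- lapply(split(df, df$genome), function(d) {
    if (nrow(d) < n)
      warning(sprintf("genome %s has only %d features with defined RTA (< %d)",
                      d$genome[1L], nrow(d), n), call. = FALSE)
    d <- d[order(-d$rta, -d$cdna_count, d$feature), , drop = FALSE]
    d <- head(d, n)
    data.frame(genome = d$genome, rank = seq_len(nrow(d)),
               feature = d$feature, rta = d$rta, cdna_count = d$cdna_count,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
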