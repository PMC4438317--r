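# Independent brute-force oracles, deliberately coded with different
# machinery (plain loops, strsplit, base table/match) than the package.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (s <= rc) s else rc
}

# per-read canonical k-mer lists (invalid windows dropped)
oracle_read_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (s in 1:(n - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    if (grepl("[^ACGT]", w)) next
    out <- c(out, oracle_canonical(w))
  }
  out
}

# dictionary of counts over a pool of sequences via base table()
oracle_count_kmers <- function(seqs, k) {
  all <- unlist(lapply(seqs, oracle_read_kmers, k = k))
  tab <- table(all)
  stats::setNames(as.integer(tab), names(tab))
}

oracle_depth <- function(seq, counts, k) {
  km <- oracle_read_kmers(seq, k)
  if (length(km) == 0) return(NA_real_)
  v <- counts[km]
  v[is.na(v)] <- 0L
  stats::median(as.numeric(v))
}

# hand-coded linear-interpolation quantile (the type-7 convention)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of the U
# distribution (tie-free samples only)
oracle_wilcoxon <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(i) sum(rank(pooled)[i]) - m * (m + 1) / 2)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# brute-force TNF: loop over 4-mer windows, pool with hand reverse
# complement, normalize
oracle_tnf <- function(seq) {
  counts <- numeric(0)
  for (s in 1:(nchar(seq) - 3)) {
    w <- substr(seq, s, s + 3)
    if (grepl("[^ACGT]", w)) next
    cw <- oracle_canonical(w)
    counts[cw] <- (if (is.na(counts[cw])) 0 else counts[cw]) + 1
  }
  counts / sum(counts)
}
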