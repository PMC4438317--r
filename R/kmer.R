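#' Count canonical k-mers across a read pool
#'
#' Counts every length-`k` window of every mate in its canonical form (the
#' lexicographic minimum of the window and its reverse complement), the
#' strand-independent convention of k-mer counters. Windows containing
#' non-ACGT symbols are skipped. This table carries the k-mer depth signal
#' used by the "divide and conquer" pre-assembly partitioning.
#'
#' @param reads a `read_set`, or a character vector of sequences.
#' @param k odd k-mer size, 3 <= k <= 63 (default 31).
#' @return An object of class `kmer_count_table`: list(k, counts) where
#'   counts is a keyed data.table (kmer, count).
#' @export
count_kmers <- function(reads, k = 31L) {
  k <- as.integer(k)
  assert_that(k %% 2L == 1L, "k must be odd (canonicalization ambiguity)")
  assert_that(k >= 3L && k <= 63L, "k must lie in [3, 63]")
  seqs <- read_sequences(reads)
  kmers <- extract_canonical_kmers(seqs, k)
  dt <- data.table(kmer = kmers)
  counts <- dt[, .N, by = "kmer"]
  setnames(counts, "N", "count")
  setkeyv(counts, "kmer")
  structure(list(k = k, counts = counts), class = "kmer_count_table")
}

read_sequences <- function(reads) {
  if (inherits(reads, "read_set")) {
    s <- c(reads$mate1, reads$mate2)
    s[!is.na(s)]
  } else as.character(reads)
}

# All canonical k-mer windows over a vector of sequences (concatenated,
# invalid windows removed). Grouped by sequence length so substring() stays
# fully vectorized.
extract_canonical_kmers <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character(0))
  out <- vector("list", 0L)
  for (L in sort(unique(nchar(seqs)))) {
    sl <- seqs[nchar(seqs) == L]
    win <- lapply(seq_len(L - k + 1L),
                  function(s) substr(sl, s, s + k - 1L))
    out[[length(out) + 1L]] <- unlist(win, use.names = FALSE)
  }
  kmers <- unlist(out, use.names = FALSE)
  bad <- grepl("[^ACGT]", kmers)
  if (any(bad)) kmers <- kmers[!bad]
  canonicalize(kmers)
}

# Vectorized count lookup; absent k-mers count 0.
kmer_counts <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_count_table"))
  idx <- table$counts[list(kmers), on = "kmer"]
  out <- idx$count
  out[is.na(out)] <- 0L
  out
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: k=%d, %d distinct k-mers, %d total\n",
              x$k, nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

#' Median k-mer depth of a read
#'
#' The per-read abundance statistic: the median of the counts of the read's
#' canonical k-mers in `table`, with absent k-mers counting 0. The median is
#' robust to the handful of erroneous k-mers a sequencing error introduces.
#'
#' @param read a single read sequence.
#' @param table a [count_kmers()] table.
#' @return The median count (numeric; may be half-integral).
#' @export
read_depth <- function(read, table) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (nchar(read) < table$k)
    stopf("read (%d bp) is shorter than k=%d and cannot be scored",
          nchar(read), table$k)
  kmers <- extract_canonical_kmers(read, table$k)
  if (length(kmers) == 0L) return(0)
  median(kmer_counts(table, kmers))
}

# Median depth for many sequences at once; NA for sequences shorter than k
# or without a single valid window.
read_depths <- function(seqs, table) {
  k <- table$k
  n <- length(seqs)
  depth <- rep(NA_real_, n)
  ok <- !is.na(seqs) & nchar(seqs) >= k
  if (!any(ok)) return(depth)
  idx <- which(ok)
  lens <- nchar(seqs[idx])
  reps <- lens - k + 1L
  long <- data.table(read = rep(idx, reps),
                     kmer = extract_kmers_keep(seqs[idx], k))
  long <- long[!grepl("[^ACGT]", long$kmer)]
  if (nrow(long) == 0L) return(depth)
  set(long, j = "kmer", value = canonicalize(long$kmer))
  set(long, j = "count", value = kmer_counts(table, long$kmer))
  med <- long[, list(depth = median(count)), by = "read"]
  depth[med$read] <- med$depth
  depth
}

# Windows in read order (including invalid ones before filtering), with one
# block per read laid out contiguously.
extract_kmers_keep <- function(seqs, k) {
  lens <- nchar(seqs)
  unlist(lapply(seq_along(seqs), function(i) {
    starts <- seq_len(lens[i] - k + 1L)
    substring(seqs[i], starts, starts + k - 1L)
  }), use.names = FALSE)
}

#' Partition read pairs by k-mer depth
#'
#' The "divide and conquer" pre-assembly split: pairs in which both mates
#' are shorter than `min_len` are discarded; each remaining pair is scored
#' by the maximum of its mates' median k-mer depths (mates shorter than
#' `min_len` or `k` do not contribute) and routed to the high-abundance
#' group when that depth reaches `depth_threshold`, otherwise to the
#' low-abundance group. Mates are never separated, preserving insert
#' information for downstream paired-end assembly. Defaults follow the
#' depth-15 / k-31 / 63-bp contract.
#'
#' @param reads a `read_set` (see [simulate_dna_reads()]).
#' @param table a [count_kmers()] table built from the same pool (or a
#'   superset).
#' @param depth_threshold minimum median depth for the high group.
#' @param min_len minimum mate length in bp.
#' @return An object of class `partition_result`: list(high, low, discarded
#'   -- each a `read_set` --, depth = per-pair depth for retained pairs,
#'   threshold, k, min_len).
#' @export
partition_reads <- function(reads, table, depth_threshold = 15L,
                            min_len = 63L) {
  stopifnot(inherits(reads, "read_set"), inherits(table, "kmer_count_table"))
  assert_that(depth_threshold >= 0, "depth_threshold must be >= 0")
  len1 <- ifelse(is.na(reads$mate1), 0L, nchar(reads$mate1))
  len2 <- ifelse(is.na(reads$mate2), 0L, nchar(reads$mate2))
  discarded <- len1 < min_len & len2 < min_len
  s1 <- ifelse(!discarded & len1 >= pmax(min_len, table$k), reads$mate1, NA)
  s2 <- ifelse(!discarded & len2 >= pmax(min_len, table$k), reads$mate2, NA)
  d1 <- read_depths(s1, table)
  d2 <- read_depths(s2, table)
  depth <- pmax(d1, d2, na.rm = TRUE)
  depth[discarded] <- NA_real_
  high <- !discarded & !is.na(depth) & depth >= depth_threshold
  low <- !discarded & !high
  subset_rs <- function(idx) {
    out <- reads[idx, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("read_set", "data.frame"),
              read_len = attr(reads, "read_len"))
  }
  structure(list(high = subset_rs(high), low = subset_rs(low),
                 discarded = subset_rs(discarded),
                 depth = depth,
                 threshold = depth_threshold, k = table$k,
                 min_len = as.integer(min_len)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "partition_result (k=%d, depth>=%d, min_len=%d): high %d, low %d, discarded %d\n",
    x$k, x$threshold, x$min_len,
    nrow(x$high), nrow(x$low), nrow(x$discarded)))
  invisible(x)
}
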