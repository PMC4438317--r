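#' @import data.table
#' @importFrom stats median mad quantile rnorm runif rlnorm rbinom sd
#'   wilcox.test cutree hclust dist cor uniroot setNames
#' @importFrom utils head write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Vectorized reverse complement for character vectors of A/C/G/T[/N] strings.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical form: lexicographic min of a k-mer and its reverse complement.
canonicalize <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# All length-k windows of one sequence (character vector, in order).
seq_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

gc_fraction <- function(seq) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq),
                                        letters = c("G", "C"))
  as.numeric(rowSums(counts)) / nchar(seq)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}
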