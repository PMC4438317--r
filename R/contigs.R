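#' Construct a contig set
#'
#' The common container for assembled or simulated contigs: a data.frame with
#' one row per contig carrying the sequence, its length, and optional
#' coverage, taxonomy and true-origin annotations (the latter only for
#' synthetic data).
#'
#' @param contig_id unique contig identifiers.
#' @param sequence contig sequences (A/C/G/T/N).
#' @param coverage optional numeric coverage per contig.
#' @param taxonomy optional taxonomy label per contig.
#' @param origin optional true-origin label (synthetic data only).
#' @param start optional 1-based start of the contig on its origin genome.
#' @return An object of class `contig_set` (a data.frame).
#' @export
contig_set <- function(contig_id, sequence, coverage = NA_real_,
                       taxonomy = NA_character_, origin = NA_character_,
                       start = NA_integer_) {
  contig_id <- as.character(contig_id)
  assert_that(!anyDuplicated(contig_id), "contig ids must be unique")
  n <- length(contig_id)
  df <- data.frame(contig_id = contig_id, sequence = as.character(sequence),
                   length = nchar(as.character(sequence)),
                   coverage = rep_len(as.numeric(coverage), n),
                   taxonomy = rep_len(as.character(taxonomy), n),
                   origin = rep_len(as.character(origin), n),
                   start = rep_len(as.integer(start), n),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("contig_set", "data.frame"))
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %d bases (%d-%d bp)\n",
              nrow(x), sum(x$length),
              if (nrow(x)) min(x$length) else 0L,
              if (nrow(x)) max(x$length) else 0L))
  invisible(x)
}

#' Split scaffolds into contigs at N-runs
#'
#' Breaks every scaffold at each maximal run of one or more 'N' characters,
#' the stringent convention that avoids propagating potentially chimeric
#' scaffold joins. Daughter contigs are named `<scaffold>_<i>` and inherit
#' the parent's coverage/taxonomy/origin annotations. Scaffolds that are all
#' N vanish; scaffolds without N pass through (renamed `<scaffold>_1`).
#'
#' @param scaffolds a [contig_set()] over the alphabet A/C/G/T/N.
#' @return A [contig_set()] of N-free contigs. Total non-N bases are
#'   preserved.
#' @export
split_scaffolds <- function(scaffolds) {
  stopifnot(inherits(scaffolds, "contig_set"))
  if (nrow(scaffolds) == 0L) return(scaffolds)
  pieces <- strsplit(scaffolds$sequence, "N+")
  out <- lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    p <- p[nzchar(p)]
    if (length(p) == 0L) return(NULL)
    data.frame(contig_id = sprintf("%s_%d", scaffolds$contig_id[i],
                                   seq_along(p)),
               sequence = p,
               coverage = scaffolds$coverage[i],
               taxonomy = scaffolds$taxonomy[i],
               origin = scaffolds$origin[i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    return(contig_set(character(0), character(0)))
  contig_set(df$contig_id, df$sequence, coverage = df$coverage,
             taxonomy = df$taxonomy, origin = df$origin)
}

# Percent-identity alignment of `short` (pattern) contained in `long`
# (subject): end-free in the subject, global in the pattern. Scoring
# match=1, mismatch=-1, linear gap -2; identity = matches / alignment
# columns (internal gaps counted).
containment_identity <- function(short, long) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(short), subject = Biostrings::DNAString(long),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  Biostrings::pid(pa, type = "PID1") / 100
}

# Cheap pre-filter: does any of a few evenly spaced 31-mers of `short`
# occur exactly in `long`? At >= 98% identity an exact 31-mer seed survives
# with probability ~0.5 per seed, so several seeds make a miss unlikely,
# while unrelated sequences essentially never trigger the full alignment.
seed_hit <- function(short, long, n_seeds = 6L, seed_len = 31L) {
  L <- nchar(short)
  if (L <= 4L * seed_len) return(TRUE)
  starts <- unique(as.integer(round(seq(1L, L - seed_len + 1L,
                                        length.out = n_seeds))))
  seeds <- substring(short, starts, starts + seed_len - 1L)
  any(vapply(seeds, function(s) grepl(s, long, fixed = TRUE), TRUE))
}

#' Remove redundant (contained) contigs
#'
#' Greedy longest-first dereplication in the style of CD-HIT with full
#' coverage of the shorter sequence: walking contigs from longest to
#' shortest, a contig is dropped when it aligns, on either strand, over
#' `short_coverage` of its own length at `identity` or better to a contig
#' already kept. Survivors are returned in input order. Defaults reproduce
#' the clustering contract -c 0.98 -aS 1 (98% identity, full alignment
#' coverage of the shorter sequence, both strands).
#'
#' @param contigs a [contig_set()].
#' @param identity minimum fractional identity, in (0.9, 1\].
#' @param short_coverage minimum fraction of the shorter contig that must be
#'   aligned (1 = containment).
#' @return A [contig_set()] of the surviving representatives, plus attribute
#'   `clusters`: a data.frame (member, representative, identity).
#' @export
dereplicate <- function(contigs, identity = 0.98, short_coverage = 1.0) {
  stopifnot(inherits(contigs, "contig_set"))
  assert_that(identity > 0.9 && identity <= 1,
              "identity must lie in (0.9, 1]")
  n <- nrow(contigs)
  if (n <= 1L) {
    attr(contigs, "clusters") <-
      data.frame(member = character(0), representative = character(0),
                 identity = numeric(0))
    return(contigs)
  }
  ord <- order(-contigs$length, seq_len(n))
  kept <- integer(0)
  clusters <- list()
  seqs <- contigs$sequence
  rcs <- revcomp(seqs)
  for (i in ord) {
    hit <- NA_integer_; hit_id <- NA_real_
    for (j in kept) {
      if (contigs$length[j] < contigs$length[i]) next
      best <- 0
      for (qry in c(seqs[i], rcs[i])) {
        if (grepl(qry, seqs[j], fixed = TRUE)) { best <- 1; break }
        if (!seed_hit(qry, seqs[j])) next
        pid <- if (short_coverage >= 1)
          containment_identity(qry, seqs[j])
        else local_identity(qry, seqs[j], short_coverage)
        best <- max(best, pid)
      }
      if (best >= identity) { hit <- j; hit_id <- best; break }
    }
    if (is.na(hit)) kept <- c(kept, i)
    else clusters[[length(clusters) + 1L]] <-
        data.frame(member = contigs$contig_id[i],
                   representative = contigs$contig_id[hit],
                   identity = hit_id, stringsAsFactors = FALSE)
  }
  out <- contigs[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, class = c("contig_set", "data.frame"))
  attr(out, "clusters") <- if (length(clusters)) do.call(rbind, clusters)
    else data.frame(member = character(0), representative = character(0),
                    identity = numeric(0))
  out
}

# Local variant used when short_coverage < 1: best local alignment must
# cover at least `cov` of the pattern.
local_identity <- function(short, long, cov) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(short), subject = Biostrings::DNAString(long),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  aligned <- Biostrings::nchar(Biostrings::alignedPattern(pa))
  if (aligned < cov * nchar(short)) return(0)
  Biostrings::pid(pa, type = "PID1") / 100
}

# Find the best suffix(A)/prefix(B) overlap of >= min_overlap bases at
# >= min_identity. Seeds with the first min_overlap bases of B (allowing
# floor(min_overlap * (1 - min_identity)) mismatches), then verifies the
# full gapless overlap. Returns NULL or list(pos, len, identity).
best_suffix_prefix <- function(A, B, min_overlap, min_identity) {
  la <- nchar(A); lb <- nchar(B)
  if (la < min_overlap || lb < min_overlap) return(NULL)
  seed <- substr(B, 1L, min_overlap)
  mm <- floor(min_overlap * (1 - min_identity))
  starts <- if (mm == 0L) {
    # exact seed: plain C string search avoids per-pair S4 overhead
    g <- gregexpr(seed, A, fixed = TRUE)[[1L]]
    if (g[1L] == -1L) integer(0) else as.integer(g)
  } else {
    BiocGenerics::start(Biostrings::matchPattern(
      seed, Biostrings::DNAString(A), max.mismatch = mm))
  }
  # only hits whose implied overlap stays within both sequences
  starts <- starts[starts >= la - lb + 1L]
  if (length(starts) == 0L) return(NULL)
  best <- NULL
  for (p in starts) {
    olen <- la - p + 1L
    a <- substr(A, p, la); b <- substr(B, 1L, olen)
    id <- mean(strsplit(a, "", fixed = TRUE)[[1L]] ==
               strsplit(b, "", fixed = TRUE)[[1L]])
    if (id >= min_identity &&
        (is.null(best) || id > best$identity ||
         (id == best$identity && olen > best$len)))
      best <- list(pos = p, len = olen, identity = id)
  }
  best
}

#' Greedily merge overlapping contigs
#'
#' Iteratively joins pairs of contigs whose suffix/prefix overlap spans at
#' least `min_overlap` bases at `min_identity` or better, considering both
#' strands, until no mergeable pair remains -- the role played by
#' Newbler/Minimus2 overlap assembly, with the same 98%/40 bp contract.
#' The highest-identity (then longest) overlap is merged first, so in a
#' cyclic overlap chain the weakest junction is the one left unmerged. At
#' disagreeing overlap positions the longer contig's bases win.
#'
#' @param contigs a [contig_set()], ideally already dereplicated.
#' @param min_identity minimum fractional overlap identity.
#' @param min_overlap minimum overlap length in bases.
#' @return A [contig_set()]; merged contigs are named by joining member ids
#'   with "+" and carry the maximum member coverage; annotations are kept
#'   when all members agree.
#' @export
merge_overlaps <- function(contigs, min_identity = 0.98, min_overlap = 40L) {
  stopifnot(inherits(contigs, "contig_set"))
  work <- data.frame(contig_id = contigs$contig_id,
                     sequence = contigs$sequence,
                     coverage = contigs$coverage,
                     taxonomy = contigs$taxonomy,
                     origin = contigs$origin,
                     stringsAsFactors = FALSE)
  repeat {
    n <- nrow(work)
    if (n <= 1L) break
    best <- NULL
    rcs <- revcomp(work$sequence)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (strand in c("+", "-")) {
        Bseq <- if (strand == "+") work$sequence[j] else rcs[j]
        ov <- best_suffix_prefix(work$sequence[i], Bseq,
                                 min_overlap, min_identity)
        if (!is.null(ov)) {
          cand <- list(i = i, j = j, strand = strand, ov = ov)
          if (is.null(best) || ov$identity > best$ov$identity ||
              (ov$identity == best$ov$identity && ov$len > best$ov$len))
            best <- cand
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j; ov <- best$ov
    A <- work$sequence[i]
    B <- if (best$strand == "+") work$sequence[j] else rcs[j]
    la <- nchar(A); lb <- nchar(B)
    merged <- if (la >= lb)
      paste0(A, substr(B, ov$len + 1L, lb))            # overlap bases from A
    else
      paste0(substr(A, 1L, ov$pos - 1L), B)            # overlap bases from B
    keep_anno <- function(x, y) if (identical(x, y)) x else NA_character_
    row <- data.frame(
      contig_id = paste(work$contig_id[i], work$contig_id[j], sep = "+"),
      sequence = merged,
      coverage = max(work$coverage[i], work$coverage[j]),
      taxonomy = keep_anno(work$taxonomy[i], work$taxonomy[j]),
      origin = keep_anno(work$origin[i], work$origin[j]),
      stringsAsFactors = FALSE)
    work <- rbind(work[-c(i, j), , drop = FALSE], row)
  }
  contig_set(work$contig_id, work$sequence, coverage = work$coverage,
             taxonomy = work$taxonomy, origin = work$origin)
}

#' Partition contigs into short and long pools by length
#'
#' Contigs shorter than `threshold` go to the short pool (historically sent
#' to Newbler), those of at least `threshold` bases to the long pool.
#'
#' @param contigs a [contig_set()].
#' @param threshold length boundary in bp; `length >= threshold` is long.
#' @return list(short = contig_set, long = contig_set).
#' @export
pool_by_length <- function(contigs, threshold = 2000L) {
  stopifnot(inherits(contigs, "contig_set"))
  is_long <- contigs$length >= threshold
  subset_cs <- function(idx) {
    out <- contigs[idx, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("contig_set", "data.frame"))
  }
  list(short = subset_cs(!is_long), long = subset_cs(is_long))
}
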