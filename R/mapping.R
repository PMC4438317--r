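# Seed index: every canonical seed_len-mer of every reference sequence,
# with its forward form, position and source. K-mers occurring in more than
# one reference are kept but flagged ambiguous; k-mers repeated within one
# reference keep their first position.
build_seed_index <- function(references, seed_len = 31L) {
  stopifnot(!is.null(names(references)))
  parts <- lapply(names(references), function(nm) {
    fwd <- seq_windows(references[[nm]], seed_len)
    data.table(canon = canonicalize(fwd), fwd = fwd,
               ref = nm, pos = seq_along(fwd))
  })
  idx <- rbindlist(parts)
  idx <- idx[!grepl("[^ACGT]", idx$fwd)]
  idx <- unique(idx, by = c("canon", "ref"))
  nref <- idx[, list(n_ref = .N), by = "canon"]
  idx <- nref[idx, on = "canon"]
  set(idx, j = "ambiguous", value = idx$n_ref > 1L)
  set(idx, j = "n_ref", value = NULL)
  idx <- unique(idx, by = "canon")   # ambiguous entries collapse to one row
  setkeyv(idx, "canon")
  structure(list(index = idx, seed_len = as.integer(seed_len),
                 ref_lengths = nchar(references)),
            class = "seed_index")
}

# Map read sequences against a seed index by exact canonical k-mer lookup.
# The seed at the read start is tried first, then the seed at the read end.
# Returns data.table(read, ref, start, end, status) with status one of
# mapped/ambiguous/unmapped; start/end are the implied reference interval.
map_with_index <- function(seqs, sidx) {
  k <- sidx$seed_len
  n <- length(seqs)
  res <- data.table(read = seq_len(n), ref = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    status = "unmapped")
  lens <- nchar(seqs)
  for (side in c("start", "end")) {
    todo <- which(res$status == "unmapped" & lens >= k)
    if (length(todo) == 0L) break
    off <- if (side == "start") rep(1L, length(todo)) else lens[todo] - k + 1L
    seed <- substring(seqs[todo], off, off + k - 1L)
    valid <- !grepl("[^ACGT]", seed)
    todo <- todo[valid]; off <- off[valid]; seed <- seed[valid]
    if (length(todo) == 0L) next
    hit <- sidx$index[list(canonicalize(seed)), on = "canon"]
    found <- !is.na(hit$ref)
    amb <- found & hit$ambiguous
    if (any(amb))
      set(res, i = todo[amb], j = "status", value = "ambiguous")
    ok <- which(found & !hit$ambiguous)
    if (length(ok) == 0L) next
    ridx <- todo[ok]
    fwd_match <- seed[ok] == hit$fwd[ok]
    p <- hit$pos[ok]; o <- off[ok]; L <- lens[ridx]
    new_start <- as.integer(ifelse(fwd_match, p - o + 1L,
                                   p + k - 1L + o - L))
    set(res, i = ridx, j = "ref", value = hit$ref[ok])
    set(res, i = ridx, j = "start", value = new_start)
    set(res, i = ridx, j = "end", value = new_start + L - 1L)
    set(res, i = ridx, j = "status", value = "mapped")
  }
  res
}

#' Map reads to genomes and gene models by exact seed matching
#'
#' A deterministic mapper for synthetic (error-free or low-error) reads: a
#' read is assigned to the unique reference containing an exact canonical
#' `seed_len`-mer match to the read's first (else last) k-mer; reads whose
#' seed occurs in more than one reference are discarded as ambiguous. A
#' mapped read is credited to a gene when the midpoint of its implied
#' reference interval falls inside the gene; otherwise it counts toward
#' the reference's intergenic total. Both mates of paired reads are mapped
#' independently.
#'
#' @param reads a `read_set`.
#' @param genomes named character vector of reference sequences.
#' @param gene_models data.frame(genome, gene_id, start, end) with 1-based
#'   inclusive, non-overlapping intervals (see [generate_community()]).
#' @param seed_len exact seed length (default 31).
#' @param index optional prebuilt seed index for `genomes` (internal reuse
#'   across read sets).
#' @return list(counts = data.frame(genome, gene_id, count) including
#'   intergenic rows with gene_id NA, read_map = data.frame(read_id, genome,
#'   gene_id, status) per mate, totals = data.frame(genome, mapped_reads,
#'   gene_reads), n_ambiguous, n_unmapped).
#' @export
map_reads_to_features <- function(reads, genomes, gene_models,
                                  seed_len = 31L, index = NULL) {
  stopifnot(inherits(reads, "read_set"))
  assert_that(all(gene_models$end <= nchar(genomes)[gene_models$genome]),
              "gene models must lie within their genomes")
  sidx <- index %||% build_seed_index(genomes, seed_len)
  seqs <- c(reads$mate1, reads$mate2)
  mate <- rep(1:2, each = nrow(reads))
  keep <- !is.na(seqs)
  seqs <- seqs[keep]
  ids <- paste0(rep(reads$read_id, 2L)[keep], "/", mate[keep])
  res <- map_with_index(seqs, sidx)
  mid <- as.integer(floor((res$start + res$end) / 2))
  gm <- as.data.table(gene_models)
  setorderv(gm, c("genome", "start"))
  gene_of <- rep(NA_character_, nrow(res))
  for (g in unique(gm$genome)) {
    sel <- which(res$status == "mapped" & res$ref == g)
    if (length(sel) == 0L) next
    gg <- gm[gm$genome == g]
    j <- findInterval(mid[sel], gg$start)
    inside <- j >= 1L & mid[sel] <= gg$end[pmax(j, 1L)]
    gene_of[sel[inside]] <- gg$gene_id[j[inside]]
  }
  read_map <- data.frame(read_id = ids, genome = res$ref,
                         gene_id = gene_of, status = res$status,
                         stringsAsFactors = FALSE)
  mappedtab <- as.data.table(read_map)[read_map$status == "mapped"]
  counts <- mappedtab[, list(count = .N), by = c("genome", "gene_id")]
  totals <- mappedtab[, list(
    mapped_reads = .N, gene_reads = sum(!is.na(gene_id))), by = "genome"]
  list(counts = as.data.frame(counts), read_map = read_map,
       totals = as.data.frame(totals),
       n_ambiguous = sum(read_map$status == "ambiguous"),
       n_unmapped = sum(read_map$status == "unmapped"))
}

#' Map reads to contigs
#'
#' Convenience wrapper mapping each read pair (mate 1 only, to keep one
#' assignment per read id) to a contig by exact canonical seed match, for
#' use with [relative_abundance()].
#'
#' @param reads a `read_set`.
#' @param contigs a [contig_set()].
#' @param seed_len exact seed length.
#' @return data.frame(read_id, contig_id) with NA for unmapped or
#'   ambiguous reads.
#' @export
map_reads_to_contigs <- function(reads, contigs, seed_len = 31L) {
  stopifnot(inherits(reads, "read_set"), inherits(contigs, "contig_set"))
  refs <- setNames(contigs$sequence, contigs$contig_id)
  res <- map_with_index(reads$mate1, build_seed_index(refs, seed_len))
  data.frame(read_id = reads$read_id,
             contig_id = ifelse(res$status == "mapped", res$ref,
                                NA_character_),
             stringsAsFactors = FALSE)
}
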