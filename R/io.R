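# File I/O: FASTA via Biostrings; FASTQ via Biostrings with constant Q30
# qualities (quality modeling is not part of the method); tables as TSV.

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

write_fastq_one <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(n) paste(rep("?", n), collapse = ""), ""))
  q <- Biostrings::QualityScaledDNAStringSet(x, qual)
  Biostrings::writeQualityScaledXStringSet(q, path)
  invisible(path)
}

#' Write a read set as FASTQ
#'
#' Paired reads go to `<prefix>_1.fastq` / `<prefix>_2.fastq`; single-end
#' sets (NA mate2) to `<prefix>.fastq`. Qualities are written as constant
#' Q30.
#'
#' @param reads a `read_set`.
#' @param prefix output path prefix.
#' @return Character vector of the files written.
#' @export
write_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) > 0 && all(is.na(reads$mate2))) {
    f <- paste0(prefix, ".fastq")
    write_fastq_one(reads$read_id, reads$mate1, f)
    return(invisible(f))
  }
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  write_fastq_one(paste0(reads$read_id, "/1"), reads$mate1, f1)
  write_fastq_one(paste0(reads$read_id, "/2"), reads$mate2, f2)
  invisible(c(f1, f2))
}

#' Read paired FASTQ files into a read set
#' @param file1,file2 mate FASTQ files; `file2 = NULL` for single-end.
#' @return A `read_set`.
#' @export
read_fastq_pairs <- function(file1, file2 = NULL) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq")
  ids <- sub("/1$", "", names(r1))
  m2 <- if (is.null(file2)) NA_character_ else
    as.character(Biostrings::readDNAStringSet(file2, format = "fastq"))
  new_read_set(data.frame(read_id = ids, mate1 = as.character(r1),
                          mate2 = m2, stringsAsFactors = FALSE),
               max(Biostrings::width(r1)))
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a contig set as FASTA plus a metadata TSV
#' @param contigs a [contig_set()].
#' @param prefix output prefix: writes `<prefix>.fasta` and
#'   `<prefix>.tsv` (contig_id, length, coverage, taxonomy, origin, start).
#' @return Character vector of files written.
#' @export
write_contigs <- function(contigs, prefix) {
  stopifnot(inherits(contigs, "contig_set"))
  fa <- paste0(prefix, ".fasta")
  write_fasta(setNames(contigs$sequence, contigs$contig_id), fa)
  tsv <- paste0(prefix, ".tsv")
  write_tsv(as.data.frame(contigs)[, c("contig_id", "length", "coverage",
                                       "taxonomy", "origin", "start")], tsv)
  invisible(c(fa, tsv))
}

#' Read a contig set written by [write_contigs()]
#' @param prefix path prefix used when writing.
#' @return A [contig_set()].
#' @export
read_contigs <- function(prefix) {
  meta <- read_tsv(paste0(prefix, ".tsv"))
  seqs <- read_fasta(paste0(prefix, ".fasta"))
  contig_set(meta$contig_id, unname(seqs[meta$contig_id]),
             coverage = meta$coverage, taxonomy = meta$taxonomy,
             origin = meta$origin, start = meta$start)
}

#' Write community ground truth to a directory
#'
#' Writes genomes (FASTA), gene models (GFF-like TSV with 1-based inclusive
#' coordinates and strand), abundances and generator parameters.
#'
#' @param truth a [generate_community()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "community_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(truth$genomes, file.path(dir, "genomes.fasta"))
  write_tsv(truth$genes, file.path(dir, "genes.tsv"))
  write_tsv(data.frame(genome = names(truth$abundances),
                       abundance = as.numeric(truth$abundances)),
            file.path(dir, "abundances.tsv"))
  jsonlite::write_json(truth$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
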