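#' Read a FASTQ file into a read table
#'
#' Reads are represented throughout the package as a plain data frame
#' with columns `read_id`, `seq` and `qual` (Sanger Phred+33 quality
#' string). Parsing is delegated to \pkg{Biostrings}.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A data frame with columns `read_id`, `seq`, `qual`.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads Data frame with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_read_table(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

check_read_table <- function(reads) {
  required <- c("read_id", "seq", "qual")
  if (!is.data.frame(reads) || !all(required %in% names(reads))) {
    format_error("reads must be a data frame with columns read_id, seq, qual")
  }
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad)) {
    format_error(sprintf(
      "sequence/quality length mismatch for record(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param sequences Named character vector, or a list of [genome()]
#'   objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.list(sequences)) {
    sequences <- setNames(
      vapply(sequences, function(g) g$sequence, character(1)),
      vapply(sequences, function(g) g$name, character(1)))
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED coordinates are 0-based, half-open, matching the package's
#' internal interval convention.
#'
#' @param path Path to a 3+ column BED file.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns", call. = FALSE)
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export alignments to SAM
#'
#' Writes ungapped single-end alignment records (CIGAR `<L>M`). Internal
#' 0-based starts are converted to SAM's 1-based `POS`; reverse-strand
#' alignments store the reverse-complemented read with FLAG 16, as SAM
#' requires.
#'
#' @param alignments Alignment data frame as produced by [map_reads()]
#'   (columns `read_id`, `start`, `strand`, `aligned_length`, `seq`;
#'   `seq` already in reference orientation).
#' @param reference_name Reference sequence name for the header.
#' @param reference_length Reference length for the header.
#' @param path Output path.
#' @param reads Optional read table providing quality strings; without
#'   it, qualities are written as `*`.
#' @return `path`, invisibly.
#' @export
export_alignments <- function(alignments, reference_name, reference_length,
                              path, reads = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", reference_name,
                       as.integer(reference_length))), con)
  if (nrow(alignments)) {
    rev <- alignments$strand == "-"
    qual <- rep("*", nrow(alignments))
    if (!is.null(reads)) {
      idx <- match(alignments$read_id, reads$read_id)
      if (anyNA(idx)) stop("alignment read ids missing from read table", call. = FALSE)
      qual <- substr(reads$qual[idx], 1L, alignments$aligned_length)
      if (any(rev)) {
        qual[rev] <- vapply(strsplit(qual[rev], ""), function(q)
          paste(rev(q), collapse = ""), character(1))
      }
    }
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                       alignments$read_id, ifelse(rev, 16L, 0L),
                       reference_name, alignments$start + 1L,
                       alignments$aligned_length, alignments$seq, qual), con)
  }
  invisible(path)
}

#' Import alignments from a SAM/BAM file
#'
#' Lets an external mapper (e.g. BWA) stand in for the built-in one.
#' Mapped records are converted to the package's alignment table;
#' unmapped records are ignored; SAM's 1-based coordinates become
#' 0-based internal starts. Read sequences are returned in reference
#' (forward) orientation as stored in the file.
#'
#' @param path Path to a SAM or BAM file.
#' @param reference_name Reference the records must belong to; an error
#'   is raised if it is absent from the file header.
#' @return A list with `alignments` (data frame: `read_id`, `reference`,
#'   `start`, `strand`, `aligned_length`, `seq`) suitable for
#'   [build_pileup()] and [breadth()].
#' @export
import_alignments <- function(path, reference_name) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!reference_name %in% names(hdr)) {
    config_error(sprintf("reference '%s' not present in alignment file header",
                         reference_name))
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "flag")))[[1]]
  keep <- !is.na(res$pos) & as.character(res$rname) == reference_name &
    bitwAnd(res$flag, 4L) == 0L
  seq <- as.character(res$seq)[keep]
  list(alignments = data.frame(
    read_id = res$qname[keep],
    reference = reference_name,
    start = res$pos[keep] - 1L,
    strand = as.character(res$strand)[keep],
    aligned_length = nchar(seq),
    seq = seq,
    stringsAsFactors = FALSE))
}
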