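#' Build an ordered reference panel
#'
#' Panel order is significant: [iterative_assign()] maps reads against
#' members in this order and removes mapped reads from the pool before
#' the next member, so earlier members take precedence (the classic
#' host-first competitive layout, e.g. host → human → bacteria →
#' spike-in virus).
#'
#' @param genomes Ordered named list of `genome` objects, or a named
#'   character vector of sequences.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(genomes) {
  if (is.character(genomes)) {
    genomes <- Map(genome, names(genomes), genomes)
  }
  nms <- vapply(genomes, function(g) g$name, character(1))
  if (anyDuplicated(nms)) stop("panel names must be unique", call. = FALSE)
  names(genomes) <- nms
  structure(list(genomes = genomes), class = "reference_panel")
}

#' Map reads to one genome
#'
#' Deterministic seed-and-extend mapping: candidate loci are exact
#' k-mer seed matches on either strand, each candidate is scored by
#' ungapped full-length extension, and the best locus is reported when
#' its identity is at least `min_identity`. Ties prefer the forward
#' strand, then the lowest start coordinate. Reads shorter than `k`
#' yield no hit (with a warning).
#'
#' @param reads Read table (`read_id`, `seq`, ...) or character vector
#'   of sequences.
#' @param genome A `genome` object or a single sequence string.
#' @param min_identity Minimum identity fraction for a reported hit.
#' @param k Seed length (default 21).
#' @param max_candidates Deterministic cap on candidate loci evaluated
#'   per read (lowest start coordinates kept).
#' @return Alignment data frame with one row per mapped read:
#'   `read_id`, `reference`, `start` (0-based), `strand`,
#'   `aligned_length`, `mismatches`, `identity` and `seq` (read bases in
#'   reference/forward orientation). The full per-read result, including
#'   unmapped reads, is attached as attribute `"per_read"`.
#' @export
map_reads <- function(reads, genome, min_identity = 0.9, k = 21L,
                      max_candidates = 50L) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  gname <- if (inherits(genome, "genome")) genome$name else "reference"
  gseq <- if (inherits(genome, "genome")) genome$sequence else genome
  res <- cpp_map_reads(reads$seq, gseq, as.integer(k), min_identity,
                       as.integer(max_candidates))
  if (any(res$short_read)) {
    warning(sprintf("%d read(s) shorter than the seed length k=%d: no hit",
                    sum(res$short_read), k), call. = FALSE)
  }
  hit <- which(res$hit)
  seq_fwd <- reads$seq[hit]
  rev <- res$strand[hit] == "-"
  if (any(rev)) seq_fwd[rev] <- reverse_complement(seq_fwd[rev])
  aln <- data.frame(read_id = reads$read_id[hit],
                    reference = rep(gname, length(hit)),
                    start = res$start[hit], strand = res$strand[hit],
                    aligned_length = res$aligned_length[hit],
                    mismatches = res$mismatches[hit],
                    identity = res$identity[hit], seq = seq_fwd,
                    stringsAsFactors = FALSE)
  attr(aln, "per_read") <- cbind(read_id = reads$read_id, res)
  aln
}

#' Map one read
#'
#' Convenience wrapper around [map_reads()] for a single sequence.
#'
#' @inheritParams map_reads
#' @param read A single read sequence.
#' @return A one-row alignment data frame, or `NULL` if the read has no
#'   hit at the required identity.
#' @export
map_read <- function(read, genome, min_identity = 0.9, k = 21L,
                     max_candidates = 50L) {
  aln <- map_reads(read, genome, min_identity = min_identity, k = k,
                   max_candidates = max_candidates)
  if (nrow(aln) == 0L) NULL else aln
}

#' Ordered competitive (iterative map-and-remove) assignment
#'
#' Maps the read pool against panel members in panel order; reads that
#' map to member *i* are removed from the pool before member *i + 1*.
#' Each read is therefore assigned to at most one reference, and the
#' per-reference counts plus the unassigned remainder always partition
#' the input.
#'
#' @param reads Read table (`read_id`, `seq`, ...).
#' @param panel A [reference_panel()].
#' @param min_identity Minimum identity for a hit.
#' @param k Seed length.
#' @return An object of class `assignment_table`: a list with
#'   `assignments` (data frame `read_id`, `reference`; `"unassigned"`
#'   for leftover reads), `counts` (data frame `reference`, `reads`,
#'   in panel order plus `unassigned`), `alignments` (named list of
#'   per-reference alignment data frames) and `n_input`.
#' @export
iterative_assign <- function(reads, panel, min_identity = 0.9, k = 21L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (length(panel$genomes) == 0L) stop("panel is empty", call. = FALSE)
  pool <- reads
  assigned <- character(nrow(reads))
  names(assigned) <- reads$read_id
  assigned[] <- "unassigned"
  alignments <- list()
  for (g in panel$genomes) {
    if (nrow(pool) == 0L) {
      alignments[[g$name]] <- empty_alignments(g$name)
      next
    }
    aln <- map_reads(pool, g, min_identity = min_identity, k = k)
    alignments[[g$name]] <- aln
    if (nrow(aln)) {
      assigned[aln$read_id] <- g$name
      pool <- pool[!pool$read_id %in% aln$read_id, , drop = FALSE]
    }
  }
  refs <- names(panel$genomes)
  counts <- data.frame(
    reference = c(refs, "unassigned"),
    reads = c(vapply(alignments[refs], nrow, integer(1)), nrow(pool)),
    stringsAsFactors = FALSE, row.names = NULL)
  stopifnot(sum(counts$reads) == nrow(reads))  # partition invariant
  structure(list(
    assignments = data.frame(read_id = reads$read_id,
                             reference = unname(assigned),
                             stringsAsFactors = FALSE),
    counts = counts, alignments = alignments, n_input = nrow(reads)),
    class = "assignment_table")
}

empty_alignments <- function(reference) {
  data.frame(read_id = character(0), reference = character(0),
             start = integer(0), strand = character(0),
             aligned_length = integer(0), mismatches = integer(0),
             identity = numeric(0), seq = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.assignment_table <- function(x, ...) {
  cat(sprintf("<assignment_table> %d reads\n", x$n_input))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
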