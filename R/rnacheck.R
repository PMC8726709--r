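#' Breadth of coverage over an interval set
#'
#' A base is covered iff at least one aligned read overlaps it; breadth
#' is the covered fraction of the interval union, in percent. Breadth is
#' invariant to read order and to duplicate alignments of the same read.
#'
#' @param alignments Alignment data frame (`start` 0-based,
#'   `aligned_length`).
#' @param intervals Data frame of 0-based half-open intervals (`start`,
#'   `end`); an empty set yields `NA` breadth.
#' @param reference_length Reference length in bases.
#' @return Data frame of class `coverage_breadth`: `covered`, `total`,
#'   `breadth` (percent).
#' @export
breadth <- function(alignments, intervals, reference_length) {
  if (nrow(intervals) == 0L) {
    res <- data.frame(covered = 0L, total = 0L, breadth = NA_real_)
    class(res) <- c("coverage_breadth", class(res))
    return(res)
  }
  if (any(intervals$start < 0) || any(intervals$end > reference_length)) {
    stop("intervals exceed reference bounds", call. = FALSE)
  }
  iv <- IRanges::reduce(IRanges::IRanges(start = intervals$start + 1L,
                                         end = intervals$end))
  total <- sum(IRanges::width(iv))
  covered <- 0L
  if (nrow(alignments)) {
    reads <- IRanges::IRanges(
      start = alignments$start + 1L,
      end = alignments$start + alignments$aligned_length)
    cov <- IRanges::coverage(reads, width = reference_length)
    covered <- sum(sum(IRanges::Views(cov > 0L, iv)))
  }
  res <- data.frame(covered = as.integer(covered), total = as.integer(total),
                    breadth = 100 * covered / total)
  class(res) <- c("coverage_breadth", class(res))
  res
}

#' Estimate the DNA-derived read fraction of an RNA library
#'
#' RNA-derived reads lie within transcribed regions, so reads mapping
#' wholly inside *non-transcribed* intervals must come from DNA
#' templates. Under uniform DNA read starts, the probability that a
#' read of length `L` falls wholly inside the non-transcribed set is
#' `E = sum(max(0, l_i - L + 1)) / (G - L + 1)` over non-transcribed
#' interval lengths `l_i`. With `w` such reads among `n` mapped reads,
#' the DNA fraction estimate is `delta_hat = min(1, (w/n) / E)`.
#' Counting only fully interior reads is conservative: RNA reads may
#' legitimately straddle interval boundaries but never lie wholly inside
#' the complement.
#'
#' @param alignments Alignment data frame for the reference (`start`
#'   0-based, `aligned_length`).
#' @param model A [transcript_model()] for the reference.
#' @param read_length Read length `L`; by default the most common
#'   aligned length (a warning is issued when lengths are mixed).
#' @param report_floor Minimum `delta_hat` for a positive verdict
#'   (default 0.01), so single stray alignments do not flag a library.
#' @param sample_id Identifier for the result.
#' @return Data frame of class `dna_carryover`: `sample`, `reference`,
#'   `w` (reads wholly inside non-transcribed intervals), `n` (mapped
#'   reads), `E` (expected interior fraction under pure DNA),
#'   `delta_hat`, `verdict` (logical), `status` (`ok` or
#'   `insufficient-data`).
#' @export
estimate_dna_fraction <- function(alignments, model, read_length = NULL,
                                  report_floor = 0.01,
                                  sample_id = "sample") {
  stopifnot(inherits(model, "transcript_model"))
  G <- model$genome_length
  nt <- non_transcribed_intervals(model)
  if (nrow(nt) == 0L) {
    stop("transcript model has no non-transcribed complement", call. = FALSE)
  }
  n <- nrow(alignments)
  if (n == 0L) {
    res <- data.frame(sample = sample_id, reference = model$genome,
                      w = 0L, n = 0L, E = NA_real_, delta_hat = NA_real_,
                      verdict = FALSE, status = "insufficient-data",
                      stringsAsFactors = FALSE)
    class(res) <- c("dna_carryover", class(res))
    return(res)
  }
  lens <- alignments$aligned_length
  if (is.null(read_length)) {
    tab <- table(lens)
    read_length <- as.integer(names(tab)[which.max(tab)])
    if (length(tab) > 1L) {
      warning("mixed aligned lengths; E uses the modal length, ",
              "interior counting uses per-read lengths", call. = FALSE)
    }
  }
  L <- read_length
  widths <- nt$end - nt$start
  E <- sum(pmax(0L, widths - L + 1L)) / (G - L + 1L)
  nt_ir <- IRanges::IRanges(start = nt$start + 1L, end = nt$end)
  reads_ir <- IRanges::IRanges(start = alignments$start + 1L,
                               end = alignments$start + lens)
  w <- sum(IRanges::countOverlaps(reads_ir, nt_ir, type = "within") > 0L)
  delta_hat <- if (E > 0) min(1, (w / n) / E) else NA_real_
  res <- data.frame(sample = sample_id, reference = model$genome,
                    w = as.integer(w), n = n, E = E, delta_hat = delta_hat,
                    verdict = isTRUE(w > 0 && !is.na(delta_hat) &&
                                       delta_hat >= report_floor),
                    status = "ok", stringsAsFactors = FALSE)
  class(res) <- c("dna_carryover", class(res))
  res
}

#' Per-base depth ratio cross-check for DNA carryover
#'
#' Complements [estimate_dna_fraction()]: the ratio of mean per-base
#' depth inside non-transcribed intervals to mean depth over the whole
#' genome. For a pure RNA library the ratio approaches 0; for pure DNA
#' it approaches 1.
#'
#' @inheritParams estimate_dna_fraction
#' @return A single numeric ratio (`NA` when there is no coverage).
#' @export
depth_ratio_nontranscribed <- function(alignments, model) {
  G <- model$genome_length
  if (nrow(alignments) == 0L) return(NA_real_)
  nt <- non_transcribed_intervals(model)
  reads_ir <- IRanges::IRanges(
    start = alignments$start + 1L,
    end = alignments$start + alignments$aligned_length)
  cov <- as.numeric(IRanges::coverage(reads_ir, width = G))
  nt_pos <- unlist(Map(function(s, e) (s + 1L):e, nt$start, nt$end))
  mean(cov[nt_pos]) / mean(cov)
}
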