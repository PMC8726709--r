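#' Quality-trimming parameters
#'
#' Defaults reproduce the common Trimmomatic-style contract
#' `SLIDINGWINDOW:4:20, MINLEN:70`: scan 5'→3' in windows of 4 bases,
#' clip at the start of the first window whose mean Phred quality drops
#' below 20, and discard reads shorter than 70 bases after clipping.
#'
#' @param window_size Window width in bases (>= 1).
#' @param quality_threshold Mean Phred quality a window must reach.
#' @param min_length Minimum retained read length in bases. This is an
#'   absolute length; for 100 bp reads it coincides with "truncated by
#'   more than 30%".
#' @param phred_offset ASCII offset of the quality encoding (33 =
#'   Sanger).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(window_size = 4L, quality_threshold = 20,
                      min_length = 70L, phred_offset = 33L) {
  if (window_size < 1L) stop("window_size must be >= 1", call. = FALSE)
  if (min_length < 1L) stop("min_length must be >= 1", call. = FALSE)
  structure(list(window_size = as.integer(window_size),
                 quality_threshold = quality_threshold,
                 min_length = as.integer(min_length),
                 phred_offset = as.integer(phred_offset)),
            class = "qc_params")
}

# Number of 5' bases kept after the sliding-window scan (0 = everything
# clipped). Windows start at every position that can hold a full
# window; reads shorter than the window are evaluated as one window.
# Trailing bases past the last full window are not re-scanned, so
# trimming is clip-at-window-start exact.
clip_point <- function(q, params) {
  len <- length(q)
  w <- params$window_size
  if (len < w) {
    return(if (mean(q) < params$quality_threshold) 0L else len)
  }
  cs <- cumsum(c(0, q))
  means <- (cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]) / w
  fail <- which(means < params$quality_threshold)
  if (length(fail)) fail[1] - 1L else len
}

#' Trim a single read by sliding-window quality
#'
#' @param seq Read sequence.
#' @param qual Quality string (same length as `seq`).
#' @param params A [qc_params()] object.
#' @return A list with `seq`, `qual` (clipped strings) and `kept`
#'   (logical; `FALSE` when the clipped read is shorter than
#'   `min_length`).
#' @examples
#' p <- qc_params()
#' r <- trim_read(strrep("A", 100),
#'                paste0(strrep("?", 80), strrep("#", 20)), p)  # Q30 then Q2
#' nchar(r$seq)  # 78
#' @export
trim_read <- function(seq, qual, params = qc_params()) {
  if (nchar(seq) != nchar(qual)) {
    stop("sequence and quality strings differ in length", call. = FALSE)
  }
  q <- utf8ToInt(qual) - params$phred_offset
  keep <- clip_point(q, params)
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep),
       kept = keep >= params$min_length)
}

#' Quality-trim a read set
#'
#' Applies [trim_read()] to every record of a FASTQ file or read table,
#' preserving input order among retained reads, and reports a summary
#' with percentages computed to one decimal.
#'
#' @param reads A read table (`read_id`, `seq`, `qual`) or a path to a
#'   FASTQ file.
#' @param params A [qc_params()] object.
#' @param output Optional path; when given, retained reads are written
#'   there as FASTQ.
#' @return A list with `reads` (retained, trimmed read table) and
#'   `summary` (data frame: `input`, `removed`, `retained`,
#'   `pct_removed`, `pct_retained`).
#' @export
run_qc <- function(reads, params = qc_params(), output = NULL) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  check_read_table(reads)
  n <- nrow(reads)
  if (n == 0L) {
    out <- reads
  } else {
    keep_len <- vapply(seq_len(n), function(i) {
      clip_point(utf8ToInt(reads$qual[i]) - params$phred_offset, params)
    }, integer(1))
    retained <- keep_len >= params$min_length
    out <- data.frame(read_id = reads$read_id[retained],
                      seq = substr(reads$seq[retained], 1L, keep_len[retained]),
                      qual = substr(reads$qual[retained], 1L, keep_len[retained]),
                      stringsAsFactors = FALSE)
  }
  removed <- n - nrow(out)
  summary <- data.frame(input = n, removed = removed, retained = nrow(out),
                        pct_removed = percent(removed, n, warn = FALSE),
                        pct_retained = percent(nrow(out), n, warn = FALSE))
  if (!is.null(output)) write_fastq(out, output)
  list(reads = out, summary = summary)
}
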