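# Independent oracle implementations used to validate the package's
# optimised code paths. These deliberately share no code with the
# implementation: the trimmer recomputes window means directly, and the
# mapper oracle scores every offset on both strands via Biostrings.

# Brute-force sliding-window trimmer: returns the number of 5' bases
# kept (0 when everything is clipped).
oracle_clip <- function(qual, window = 4L, threshold = 20,
                        min_length = 70L, offset = 33L) {
  q <- utf8ToInt(qual) - offset
  len <- length(q)
  if (len < window) {
    keep <- if (sum(q) / len < threshold) 0L else len
  } else {
    keep <- len
    for (s in 1:(len - window + 1)) {
      if (sum(q[s:(s + window - 1)]) / window < threshold) {
        keep <- s - 1L
        break
      }
    }
  }
  keep
}

# Exhaustive all-offset, both-strand ungapped scorer. Ties are broken
# like the mapper's contract: forward strand first, then lowest start.
oracle_map <- function(read, genome_seq, min_identity = 0.9) {
  L <- nchar(read)
  G <- nchar(genome_seq)
  if (L > G) return(NULL)
  subject <- Biostrings::DNAString(genome_seq)
  offsets <- 1:(G - L + 1)
  best <- NULL
  for (st in c("+", "-")) {
    pat <- Biostrings::DNAString(read)
    if (st == "-") pat <- Biostrings::reverseComplement(pat)
    mm <- Biostrings::neditStartingAt(pat, subject, starting.at = offsets,
                                      with.indels = FALSE)
    i <- which.min(mm)  # lowest start among minima
    cand <- list(start = offsets[i] - 1L, strand = st, mismatches = mm[i],
                 identity = 1 - mm[i] / L)
    if (is.null(best) || cand$mismatches < best$mismatches) best <- cand
  }
  if (best$identity < min_identity) NULL else best
}

random_quality <- function(len, lo = 2L, hi = 40L) {
  intToUtf8(sample(lo:hi, len, replace = TRUE) + 33L)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Draw a read from a genome with i.i.d. substitution errors, optionally
# reverse-complemented, for mapper tests.
draw_read <- function(genome_seq, len, error_rate = 0, revcomp = FALSE) {
  G <- nchar(genome_seq)
  pos <- sample.int(G - len + 1L, 1L)
  seq <- substr(genome_seq, pos, pos + len - 1L)
  if (error_rate > 0) {
    chars <- strsplit(seq, "")[[1]]
    err <- which(runif(len) < error_rate)
    for (i in err) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    seq <- paste(chars, collapse = "")
  }
  if (revcomp) {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  list(seq = seq, pos = pos - 1L, strand = if (revcomp) "-" else "+")
}

# Alignments straight from a simulation truth table (reads are simulated
# from the forward strand), bypassing the mapper where only downstream
# modules are under test.
alignments_from_truth <- function(sim, source_ids, reference_name) {
  keep <- which(sim$truth$source %in% source_ids)
  data.frame(read_id = sim$truth$read_id[keep],
             reference = rep(reference_name, length(keep)),
             start = sim$truth$position[keep],
             strand = rep("+", length(keep)),
             aligned_length = nchar(sim$reads$seq[keep]),
             mismatches = rep(NA_integer_, length(keep)),
             identity = rep(NA_real_, length(keep)),
             seq = sim$reads$seq[keep],
             stringsAsFactors = FALSE)
}

empty_aln <- function() {
  data.frame(read_id = character(0), reference = character(0),
             start = integer(0), strand = character(0),
             aligned_length = integer(0), seq = character(0))
}
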