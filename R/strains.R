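#' Build a base-count pileup from ungapped alignments
#'
#' Tallies every aligned base once into per-position A/C/G/T counts.
#' Alignment sequences must already be in reference orientation (as
#' produced by [map_reads()] and [import_alignments()]).
#'
#' @param alignments Alignment data frame (`start` 0-based,
#'   `aligned_length`, `seq`).
#' @param reference A `genome` object or sequence string.
#' @return An object of class `pileup`: list with `reference` (name),
#'   `counts` (4 x G integer matrix, rows A/C/G/T) and `depth`
#'   (integer vector of length G).
#' @export
build_pileup <- function(alignments, reference) {
  gname <- if (inherits(reference, "genome")) reference$name else "reference"
  gseq <- if (inherits(reference, "genome")) reference$sequence else reference
  G <- nchar(gseq)
  if (nrow(alignments) &&
      any(alignments$start < 0 |
          alignments$start + alignments$aligned_length > G)) {
    stop("alignment exceeds reference bounds", call. = FALSE)
  }
  counts <- matrix(0L, nrow = 4, ncol = G,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (nrow(alignments)) {
    lens <- alignments$aligned_length
    pos <- sequence(lens, from = alignments$start + 1L)  # 1-based
    bases <- unlist(strsplit(alignments$seq, ""), use.names = FALSE)
    code <- match(bases, c("A", "C", "G", "T"))
    ok <- !is.na(code)
    idx <- (pos[ok] - 1L) * 4L + code[ok]
    tab <- tabulate(idx, nbins = 4L * G)
    counts[] <- tab
  }
  structure(list(reference = gname, counts = counts,
                 depth = as.integer(colSums(counts))),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d positions, mean depth %.1f\n",
              x$reference, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Call consensus single-nucleotide variants from a pileup
#'
#' A position is a consensus SNV iff its depth is at least `cmin` and
#' the most frequent non-reference allele reaches frequency `fcons`
#' (which must exceed 0.5, so the call is the sample's major allele).
#' All positions with depth >= `cmin` form the callable-site mask.
#'
#' @param pileup A [build_pileup()] result.
#' @param reference_seq Reference sequence string (or `genome`).
#' @param sample_id Identifier stored in the profile.
#' @param fcons Consensus frequency threshold (> 0.5; default 0.8).
#' @param cmin Minimum depth for a callable site (default 5).
#' @return An object of class `snv_profile`: list with `reference`,
#'   `sample_id`, `variants` (data frame `pos` 0-based, `ref`, `alt`,
#'   `freq`, `depth`) and `callable` (logical vector over positions).
#' @export
call_snvs <- function(pileup, reference_seq, sample_id = "sample",
                      fcons = 0.8, cmin = 5L) {
  if (fcons <= 0.5) stop("fcons must exceed 0.5", call. = FALSE)
  if (inherits(reference_seq, "genome")) reference_seq <- reference_seq$sequence
  G <- length(pileup$depth)
  stopifnot(nchar(reference_seq) == G)
  callable <- pileup$depth >= cmin
  ref_chars <- strsplit(reference_seq, "")[[1]]
  ref_code <- match(ref_chars, c("A", "C", "G", "T"))
  cnt <- pileup$counts
  # zero out the reference allele, take the best remaining allele
  nonref <- cnt
  nonref[cbind(ref_code, seq_len(G))] <- -1L
  best_code <- max.col(t(nonref), ties.method = "first")
  best_cnt <- nonref[cbind(best_code, seq_len(G))]
  freq <- ifelse(pileup$depth > 0, best_cnt / pileup$depth, 0)
  is_var <- callable & freq >= fcons & best_cnt > 0
  variants <- data.frame(
    pos = which(is_var) - 1L,
    ref = ref_chars[is_var],
    alt = c("A", "C", "G", "T")[best_code[is_var]],
    freq = freq[is_var],
    depth = pileup$depth[is_var],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(reference = pileup$reference, sample_id = sample_id,
                 variants = variants, callable = callable,
                 reference_seq = reference_seq),
            class = "snv_profile")
}

#' @export
print.snv_profile <- function(x, ...) {
  cat(sprintf("<snv_profile> %s on %s: %d variants, %d callable sites\n",
              x$sample_id, x$reference, nrow(x$variants), sum(x$callable)))
  invisible(x)
}

#' Write an SNV profile as a VCF-like TSV
#'
#' Columns CHROM, POS (1-based on output), REF, ALT, AF, DP.
#'
#' @param profile An `snv_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_profile <- function(profile, path) {
  v <- profile$variants
  write_tsv(data.frame(CHROM = rep(profile$reference, nrow(v)),
                       POS = v$pos + 1L,
                       REF = v$ref, ALT = v$alt, AF = round(v$freq, 4),
                       DP = v$depth, stringsAsFactors = FALSE), path)
}

# Major allele of a profile at given 0-based positions: the variant alt
# where a variant is recorded, otherwise the reference base.
major_allele_at <- function(profile, pos0) {
  out <- substring(profile$reference_seq, pos0 + 1L, pos0 + 1L)
  hit <- match(pos0, profile$variants$pos)
  out[!is.na(hit)] <- profile$variants$alt[hit[!is.na(hit)]]
  out
}

#' Score strain sharing between two SNV profiles
#'
#' Comparable sites are positions callable in both samples and variant
#' in at least one. Agreement is the fraction of comparable sites whose
#' major alleles are identical. The verdict is `same-strain` when at
#' least `m_min` comparable sites agree at a fraction of at least
#' `agreement_threshold`, `distinct` when enough sites disagree, and
#' `insufficient-data` when fewer than `m_min` sites are comparable.
#' The score is symmetric in its two arguments.
#'
#' @param a,b `snv_profile`s against the same reference.
#' @param m_min Minimum comparable sites for a verdict (default 10).
#' @param agreement_threshold Agreement fraction required for
#'   `same-strain` (default 0.99).
#' @return Data frame of class `share_result`: `sample_a`, `sample_b`,
#'   `m` (comparable sites), `agreeing`, `agreement`, `verdict`.
#' @export
share_score <- function(a, b, m_min = 10L, agreement_threshold = 0.99) {
  stopifnot(inherits(a, "snv_profile"), inherits(b, "snv_profile"))
  if (a$reference != b$reference) {
    stop("profiles refer to different references", call. = FALSE)
  }
  both_callable <- which(a$callable & b$callable) - 1L
  var_any <- union(a$variants$pos, b$variants$pos)
  comparable <- intersect(both_callable, var_any)
  m <- length(comparable)
  if (m < m_min) {
    res <- data.frame(sample_a = a$sample_id, sample_b = b$sample_id,
                      m = m, agreeing = NA_integer_, agreement = NA_real_,
                      verdict = "insufficient-data", stringsAsFactors = FALSE)
  } else {
    agree <- major_allele_at(a, comparable) == major_allele_at(b, comparable)
    frac <- mean(agree)
    res <- data.frame(sample_a = a$sample_id, sample_b = b$sample_id,
                      m = m, agreeing = sum(agree), agreement = frac,
                      verdict = if (frac >= agreement_threshold)
                        "same-strain" else "distinct",
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("share_result", class(res))
  res
}

#' Detect a within-sample strain mixture
#'
#' A pure strain shows only sequencing-error noise at callable sites; a
#' mixture of two related strains shows a coherent band of
#' intermediate-frequency minor alleles at their discriminating sites.
#' The sample is called a `mixture` when at least `site_min` positions
#' of depth >= `cmin` carry a minor-allele frequency inside `band`.
#' The mean and SD of those frequencies are reported; a small SD
#' (frequency coherence) supports a two-strain interpretation.
#'
#' @param pileup A [build_pileup()] result.
#' @param band Numeric length-2: inclusive minor-allele frequency band
#'   (default `c(0.2, 0.8)`).
#' @param site_min Minimum intermediate sites for a mixture call
#'   (default 5).
#' @param cmin Minimum depth (default 5).
#' @param sd_threshold SD below which the intermediate frequencies are
#'   reported as coherent (default 0.15).
#' @param min_minor_count Minimum number of reads supporting the minor
#'   allele for a site to count as intermediate (default 2): a singleton
#'   read cannot support a mixture, so this guards low-depth sites
#'   against single sequencing errors.
#' @param sample_id Identifier for the result.
#' @return Data frame of class `mixture_call`: `sample`, `reference`,
#'   `n_sites` (intermediate-frequency sites), `mean_minor_freq`,
#'   `sd_minor_freq`, `coherent`, `verdict` (`single`/`mixture`/
#'   `insufficient-data`).
#' @export
detect_mixture <- function(pileup, band = c(0.2, 0.8), site_min = 5L,
                           cmin = 5L, sd_threshold = 0.15,
                           min_minor_count = 2L, sample_id = "sample") {
  stopifnot(length(band) == 2, band[1] > 0, band[2] < 1, band[1] < band[2])
  depth <- pileup$depth
  callable <- which(depth >= cmin)
  if (!length(callable)) {
    res <- data.frame(sample = sample_id, reference = pileup$reference,
                      n_sites = 0L, mean_minor_freq = NA_real_,
                      sd_minor_freq = NA_real_, coherent = NA,
                      verdict = "insufficient-data", stringsAsFactors = FALSE)
    class(res) <- c("mixture_call", class(res))
    return(res)
  }
  cnt <- pileup$counts[, callable, drop = FALSE]
  # minor allele = second most frequent base
  minor_count <- apply(cnt, 2, function(x) sort(x, decreasing = TRUE)[2])
  minor_freq <- minor_count / depth[callable]
  inband <- minor_freq >= band[1] & minor_freq <= band[2] &
    minor_count >= min_minor_count
  n_sites <- sum(inband)
  mf <- minor_freq[inband]
  res <- data.frame(
    sample = sample_id, reference = pileup$reference, n_sites = n_sites,
    mean_minor_freq = if (n_sites) mean(mf) else NA_real_,
    sd_minor_freq = if (n_sites > 1) stats::sd(mf) else NA_real_,
    coherent = if (n_sites > 1) stats::sd(mf) <= sd_threshold else NA,
    verdict = if (n_sites >= site_min) "mixture" else "single",
    stringsAsFactors = FALSE)
  class(res) <- c("mixture_call", class(res))
  res
}

#' Consensus average nucleotide identity against the reference
#'
#' Compares the sample's consensus base (most frequent allele; ties go
#' to the reference base, then alphabetical order) to the reference at
#' every position with depth >= `cmin`.
#'
#' @param pileup A [build_pileup()] result.
#' @param reference_seq Reference sequence string (or `genome`).
#' @param cmin Minimum depth for a compared position (default 5).
#' @param sample_id Identifier for the result.
#' @return Data frame of class `ani_result`: `sample`, `reference`,
#'   `compared`, `identical`, `ani` (percent; `NA` with verdict
#'   `insufficient-data` when nothing is compared).
#' @export
consensus_ani <- function(pileup, reference_seq, cmin = 5L,
                          sample_id = "sample") {
  if (inherits(reference_seq, "genome")) reference_seq <- reference_seq$sequence
  G <- length(pileup$depth)
  stopifnot(nchar(reference_seq) == G)
  callable <- which(pileup$depth >= cmin)
  if (!length(callable)) {
    res <- data.frame(sample = sample_id, reference = pileup$reference,
                      compared = 0L, identical = 0L, ani = NA_real_,
                      verdict = "insufficient-data", stringsAsFactors = FALSE)
    class(res) <- c("ani_result", class(res))
    return(res)
  }
  ref_chars <- strsplit(reference_seq, "")[[1]][callable]
  ref_code <- match(ref_chars, c("A", "C", "G", "T"))
  cnt <- pileup$counts[, callable, drop = FALSE]
  # tie-break toward the reference: give its allele an epsilon bonus
  cnt_adj <- cnt + 1e-9
  cnt_adj[cbind(ref_code, seq_along(callable))] <-
    cnt_adj[cbind(ref_code, seq_along(callable))] + 1e-6
  cons_code <- max.col(t(cnt_adj), ties.method = "first")
  identical_n <- sum(cons_code == ref_code)
  res <- data.frame(sample = sample_id, reference = pileup$reference,
                    compared = length(callable), identical = identical_n,
                    ani = 100 * identical_n / length(callable),
                    verdict = "ok", stringsAsFactors = FALSE)
  class(res) <- c("ani_result", class(res))
  res
}
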