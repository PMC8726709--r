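#' Percentage with table-style rounding
#'
#' Computes `100 * numerator / denominator` rounded half away from zero
#' to one decimal — the convention used when printing read-accounting
#' tables (e.g. 48,122 of 167,841 reads → 28.7). A zero denominator
#' yields 0.0 with a warning.
#'
#' @param numerator,denominator Non-negative counts (vectorised).
#' @param warn Emit a warning for zero denominators.
#' @return Numeric vector of percentages with one decimal.
#' @examples
#' percent(48122, 167841)      # 28.7
#' percent(74205991, 77298225) # 96.0
#' @export
percent <- function(numerator, denominator, warn = TRUE) {
  if (any(numerator < 0) || any(denominator < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- numeric(length(numerator))
  zero <- denominator == 0
  if (any(zero) && warn) warning("zero denominator; reporting 0.0", call. = FALSE)
  p <- 100 * numerator[!zero] / denominator[!zero]
  out[!zero] <- sign(p) * floor(abs(p) * 10 + 0.5) / 10
  out
}

#' Read-accounting rows in host-first table layout
#'
#' Combines QC summaries and competitive-assignment counts into one row
#' per library: raw reads, low-quality removed, host-mapped reads (the
#' first panel reference), the filtered (non-host) remainder, and
#' per-taxon counts. Percentages follow the dual-denominator
#' convention: the host percentage is relative to quality-retained
#' reads, every other taxon is relative to the filtered (host-depleted)
#' read count, and the filtered count itself is shown relative to raw
#' input.
#'
#' @param qc_summaries Named list (by `<sample_id>_<library>`) of QC
#'   summary data frames from [run_qc()].
#' @param assignments Named list (same keys) of `assignment_table`s
#'   from [iterative_assign()].
#' @param host Name of the host reference (default: first reference of
#'   the first assignment table).
#' @return Data frame of class `accounting` with one row per library:
#'   `sample`, `raw`, `removed`, `retained`, `host`, `pct_host`,
#'   `filtered`, `pct_filtered`, then `<taxon>` and `pct_<taxon>`
#'   columns, and `unassigned`.
#' @export
build_accounting <- function(qc_summaries, assignments, host = NULL) {
  keys <- names(qc_summaries)
  missing <- setdiff(keys, names(assignments))
  if (length(missing)) {
    stop(sprintf("missing assignment table(s) for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  refs <- assignments[[1]]$counts$reference
  refs <- refs[refs != "unassigned"]
  if (is.null(host)) host <- refs[1]
  taxa <- setdiff(refs, host)

  rows <- lapply(keys, function(key) {
    qs <- qc_summaries[[key]]
    at <- assignments[[key]]
    cnt <- setNames(at$counts$reads, at$counts$reference)
    raw <- qs$input
    retained <- qs$retained
    stopifnot(raw == qs$removed + retained,
              at$n_input == retained)
    host_n <- unname(cnt[host])
    filtered <- retained - host_n
    row <- data.frame(sample = key, raw = raw, removed = qs$removed,
                      retained = retained, host = host_n,
                      pct_host = percent(host_n, retained, warn = FALSE),
                      filtered = filtered,
                      pct_filtered = percent(filtered, raw, warn = FALSE),
                      stringsAsFactors = FALSE)
    for (t in taxa) {
      row[[t]] <- unname(cnt[t])
      row[[paste0("pct_", t)]] <- percent(unname(cnt[t]), filtered,
                                          warn = FALSE)
    }
    row$unassigned <- unname(cnt["unassigned"])
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "host") <- host
  attr(out, "taxa") <- taxa
  class(out) <- c("accounting", class(out))
  out
}

#' Dual-denominator relative-abundance profiles
#'
#' @param accounting An `accounting` table from [build_accounting()].
#' @return Data frame with one row per library: `sample`, `pct_host`
#'   (denominator: quality-retained reads) and one `pct_<taxon>` column
#'   per non-host taxon (denominator: filtered, host-depleted reads).
#' @export
abundance_profile <- function(accounting) {
  taxa <- attr(accounting, "taxa")
  cols <- c("sample", "pct_host", paste0("pct_", taxa))
  out <- accounting[, cols]
  attr(out, "taxa") <- taxa
  out
}

#' Negative-control fold-change filter parameters
#'
#' @param log2_fold_threshold Minimum `log2` fold change of mean
#'   specimen abundance over the negative control for a taxon to be
#'   kept (default 2, i.e. a strict > 4-fold rule).
#' @param pseudocount Pseudocount in reads, converted to the abundance
#'   (percent) scale via each side's denominator.
#' @return An object of class `control_filter_params`.
#' @export
control_filter_params <- function(log2_fold_threshold = 2, pseudocount = 1) {
  if (log2_fold_threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  structure(list(log2_fold_threshold = log2_fold_threshold,
                 pseudocount = pseudocount),
            class = "control_filter_params")
}

#' Negative-control fold-change filter
#'
#' Reimplements the contaminant filter used in gene-centric microbiome
#' pipelines at the taxon level: a taxon is kept iff
#' `log2((mean + eps_s) / (control + eps_c)) > threshold`, i.e. at the
#' default threshold iff its mean specimen abundance is more than 4-fold
#' the negative-control abundance. The pseudocount (1 read by default)
#' is converted to the percent scale through the supplied denominators
#' and guards against zero-abundance controls.
#'
#' @param specimen_abundance Named numeric vector of mean specimen
#'   abundances (percent), or a samples-by-taxa matrix/data frame whose
#'   column means are used.
#' @param control_abundance Named numeric vector: negative-control
#'   abundance per taxon (same taxa).
#' @param params A [control_filter_params()].
#' @param specimen_reads,control_reads Denominator read counts used to
#'   convert the pseudocount to the percent scale (default `1e4`).
#' @return Data frame (`taxon`, `mean_abundance`, `control_abundance`,
#'   `log2_fold`, `kept`).
#' @export
control_filter <- function(specimen_abundance, control_abundance,
                           params = control_filter_params(),
                           specimen_reads = 1e4, control_reads = 1e4) {
  if (is.matrix(specimen_abundance) || is.data.frame(specimen_abundance)) {
    specimen_abundance <- colMeans(as.matrix(specimen_abundance))
  }
  if (any(specimen_abundance < 0) || any(control_abundance < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  taxa <- names(specimen_abundance)
  if (!setequal(taxa, names(control_abundance))) {
    stop("specimen and control taxon sets differ", call. = FALSE)
  }
  control_abundance <- control_abundance[taxa]
  eps_s <- 100 * params$pseudocount / specimen_reads
  eps_c <- 100 * params$pseudocount / control_reads
  l2 <- log2((specimen_abundance + eps_s) / (control_abundance + eps_c))
  data.frame(taxon = taxa, mean_abundance = unname(specimen_abundance),
             control_abundance = unname(control_abundance),
             log2_fold = unname(l2),
             kept = unname(l2 > params$log2_fold_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag samples whose profile is explainable by the negative control
#'
#' A sample is suspicious when every taxon it contains is detected at an
#' abundance within `kc`-fold of — or below — the negative control's
#' abundance for that taxon: nothing in the sample rises convincingly
#' above background. Samples with no detected non-host taxa are flagged
#' with a "no signal above control" annotation.
#'
#' @param profiles Data frame from [abundance_profile()] (or a matrix of
#'   percent abundances with samples as rows and taxa as columns).
#' @param control_sample Row name/`sample` value of the negative
#'   control within `profiles`, or a named numeric vector of control
#'   abundances.
#' @param kc Comparability fold (default 4).
#' @return Data frame (`sample`, `flagged`, `annotation`,
#'   `offending_taxa`): `offending_taxa` lists taxa above `kc`-fold of
#'   the control (evidence *against* contamination) for unflagged
#'   samples, and the supporting taxa for flagged ones.
#' @export
control_similarity_flag <- function(profiles, control_sample, kc = 4) {
  if (is.data.frame(profiles) && "sample" %in% names(profiles)) {
    taxa <- attr(profiles, "taxa")
    if (is.null(taxa)) {
      taxa <- sub("^pct_", "", grep("^pct_", names(profiles), value = TRUE))
      taxa <- setdiff(taxa, "host")
    }
    m <- as.matrix(profiles[, paste0("pct_", taxa), drop = FALSE])
    rownames(m) <- profiles$sample
    colnames(m) <- taxa
  } else {
    m <- as.matrix(profiles)
    taxa <- colnames(m)
  }
  if (is.character(control_sample)) {
    if (!control_sample %in% rownames(m)) {
      stop(sprintf("negative control '%s' absent from profiles",
                   control_sample), call. = FALSE)
    }
    control <- m[control_sample, ]
    m <- m[setdiff(rownames(m), control_sample), , drop = FALSE]
  } else {
    control <- control_sample[taxa]
  }
  rows <- lapply(rownames(m), function(s) {
    ab <- m[s, ]
    detected <- ab > 0
    if (!any(detected)) {
      return(data.frame(sample = s, flagged = TRUE,
                        annotation = "no signal above control",
                        offending_taxa = "", stringsAsFactors = FALSE))
    }
    within <- ab[detected] <= kc * control[detected]
    if (all(within)) {
      data.frame(sample = s, flagged = TRUE,
                 annotation = sprintf(
                   "all %d detected taxa within %g-fold of negative control",
                   sum(detected), kc),
                 offending_taxa = paste(names(which(detected)), collapse = ";"),
                 stringsAsFactors = FALSE)
    } else {
      above <- names(which(detected))[!within]
      data.frame(sample = s, flagged = FALSE,
                 annotation = sprintf(
                   "%d taxa exceed %g-fold of negative control",
                   length(above), kc),
                 offending_taxa = paste(above, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
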