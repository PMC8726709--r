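#' Default pipeline parameters
#'
#' Collects every tunable threshold of the downstream stages in one
#' list so a run is fully described by (study design, parameters, seed).
#'
#' @param qc [qc_params()] for quality trimming.
#' @param min_identity,k Mapper stringency and seed length.
#' @param fcons,cmin SNV-calling consensus frequency and minimum depth.
#' @param m_min,agreement_threshold Strain-sharing verdict thresholds.
#' @param band,site_min Mixture-detection minor-frequency band and site
#'   minimum.
#' @param kc Comparability fold for the control-similarity flag.
#' @param filter [control_filter_params()] for the fold-change filter.
#' @param carryover_floor Reporting floor for the DNA-carryover verdict.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(qc = qc_params(), min_identity = 0.9, k = 21L,
                            fcons = 0.8, cmin = 5L, m_min = 10L,
                            agreement_threshold = 0.99,
                            band = c(0.2, 0.8), site_min = 5L, kc = 4,
                            filter = control_filter_params(),
                            carryover_floor = 0.01) {
  structure(list(qc = qc, min_identity = min_identity, k = as.integer(k),
                 fcons = fcons, cmin = as.integer(cmin),
                 m_min = as.integer(m_min),
                 agreement_threshold = agreement_threshold, band = band,
                 site_min = as.integer(site_min), kc = kc, filter = filter,
                 carryover_floor = carryover_floor),
            class = "pipeline_params")
}

#' Run the full contamination-forensics pipeline on a study
#'
#' Executes simulate → qc → competitive mapping → abundance accounting →
#' strain analysis → DNA-carryover check → verdict report. The run is
#' deterministic for a fixed study design (which carries the seed).
#'
#' @param study A `study_design` (see [study_design_default()]), or a
#'   pre-simulated result from [simulate_study()].
#' @param params A [pipeline_params()] list.
#' @param outdir Optional directory; when given, every intermediate
#'   table and the verdict report are written as TSV.
#' @return A list of class `pipeline_result` with elements
#'   `qc_summaries`, `assignments`, `accounting`, `profiles`,
#'   `similarity` (per library type), `filter_report`, `snv_profiles`,
#'   `share`, `mixtures`, `ani`, `carryover` and `report`.
#' @export
run_pipeline <- function(study, params = pipeline_params(), outdir = NULL) {
  sim <- if (inherits(study, "study_design")) simulate_study(study) else study
  panel <- reference_panel(sim$panel)
  designs <- sim$designs
  keys <- vapply(designs, function(d)
    paste(d$sample_id, d$library, sep = "_"), character(1))

  # qc + competitive assignment per library
  qc_summaries <- list(); assignments <- list()
  for (i in seq_along(designs)) {
    key <- keys[i]
    qc <- run_qc(sim$libraries[[key]]$reads, params$qc)
    qc_summaries[[key]] <- qc$summary
    assignments[[key]] <- iterative_assign(qc$reads, panel,
                                           min_identity = params$min_identity,
                                           k = params$k)
  }

  accounting <- build_accounting(qc_summaries, assignments)
  profiles <- abundance_profile(accounting)
  taxa <- attr(accounting, "taxa")

  roles <- setNames(vapply(designs, function(d) d$role, character(1)), keys)
  libtypes <- setNames(vapply(designs, function(d) d$library, character(1)),
                       keys)
  neg_keys <- keys[roles == "negative_control"]

  # control-similarity flags, separately per library type
  similarity <- list()
  for (lt in unique(libtypes)) {
    neg <- neg_keys[libtypes[neg_keys] == lt]
    if (length(neg) != 1L) next
    sub <- profiles[profiles$sample %in% keys[libtypes == lt], ]
    attr(sub, "taxa") <- taxa
    similarity[[lt]] <- control_similarity_flag(sub, neg, kc = params$kc)
  }
  similarity_tab <- do.call(rbind, similarity)

  # taxon-level fold-change filter (DNA specimens vs DNA negative control)
  filter_report <- NULL
  spec_dna <- keys[roles == "specimen" & libtypes == "DNA"]
  neg_dna <- neg_keys[libtypes[neg_keys] == "DNA"]
  if (length(spec_dna) && length(neg_dna) == 1L) {
    spec_m <- as.matrix(profiles[match(spec_dna, profiles$sample),
                                 paste0("pct_", taxa), drop = FALSE])
    colnames(spec_m) <- taxa
    ctrl <- setNames(as.numeric(
      profiles[match(neg_dna, profiles$sample), paste0("pct_", taxa)]), taxa)
    filter_report <- control_filter(
      spec_m, ctrl, params$filter,
      specimen_reads = mean(accounting$filtered[match(spec_dna,
                                                      accounting$sample)]),
      control_reads = accounting$filtered[match(neg_dna, accounting$sample)])
  }

  # strain analysis per reference
  snv_profiles <- list(); share <- list(); mixtures <- list(); ani <- list()
  for (ref in names(panel$genomes)) {
    g <- panel$genomes[[ref]]
    for (key in keys) {
      aln <- assignments[[key]]$alignments[[ref]]
      if (nrow(aln) == 0L) next
      pu <- build_pileup(aln, g)
      snv_profiles[[ref]][[key]] <- call_snvs(pu, g, sample_id = key,
                                              fcons = params$fcons,
                                              cmin = params$cmin)
      mixtures[[length(mixtures) + 1L]] <-
        detect_mixture(pu, band = params$band, site_min = params$site_min,
                       cmin = params$cmin, sample_id = key)
      ani[[length(ani) + 1L]] <- consensus_ani(pu, g, cmin = params$cmin,
                                               sample_id = key)
    }
    prof <- snv_profiles[[ref]]
    if (length(prof) >= 2L) {
      ks <- names(prof)
      for (i in seq_along(ks)[-length(ks)]) {
        for (j in (i + 1):length(ks)) {
          s <- share_score(prof[[ks[i]]], prof[[ks[j]]],
                           m_min = params$m_min,
                           agreement_threshold = params$agreement_threshold)
          s$reference <- ref
          share[[length(share) + 1L]] <- s
        }
      }
    }
  }
  share_tab <- if (length(share)) do.call(rbind, share) else NULL
  mixture_tab <- if (length(mixtures)) do.call(rbind, mixtures) else NULL
  ani_tab <- if (length(ani)) do.call(rbind, ani) else NULL

  # DNA carryover for RNA libraries, per reference with a transcript model
  carryover <- list()
  for (key in keys[libtypes == "RNA"]) {
    for (ref in names(panel$genomes)) {
      model <- sim$transcripts[[ref]]
      if (is.null(model)) next
      aln <- assignments[[key]]$alignments[[ref]]
      if (nrow(aln) < 50L) next  # too few mapped reads to say anything
      res <- estimate_dna_fraction(aln, model,
                                   report_floor = params$carryover_floor,
                                   sample_id = key)
      carryover[[length(carryover) + 1L]] <- res
    }
  }
  carryover_tab <- if (length(carryover)) do.call(rbind, carryover) else NULL

  report <- build_report(keys = keys, roles = roles, libtypes = libtypes,
                         similarity = similarity_tab, share = share_tab,
                         carryover = carryover_tab)

  result <- structure(list(
    qc_summaries = qc_summaries, assignments = assignments,
    accounting = accounting, profiles = profiles,
    similarity = similarity_tab, filter_report = filter_report,
    snv_profiles = snv_profiles, share = share_tab, mixtures = mixture_tab,
    ani = ani_tab, carryover = carryover_tab, report = report),
    class = "pipeline_result")

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' Combine the three evidence classes into a per-sample verdict
#'
#' A sample is "suspect contamination" when at least one evidence line
#' is present: (1) its abundance profile is explainable by the negative
#' control, (2) it shares a strain (same-strain SNV profile) with a
#' control or with another sample, or (3) its RNA library contains
#' DNA-derived reads (coverage wholly inside non-transcribed regions).
#' Missing stages degrade gracefully: absent tables simply contribute no
#' evidence.
#'
#' @param keys Library keys (`<sample_id>_<library>`).
#' @param roles,libtypes Named character vectors over `keys`.
#' @param similarity Control-similarity table (or `NULL`).
#' @param share Strain-sharing table (or `NULL`).
#' @param carryover DNA-carryover table (or `NULL`).
#' @return Data frame of class `verdict_report`: one row per sample with
#'   logical evidence flags, the overall `suspect` flag and
#'   pipe-separated `evidence` lines citing the producing module.
#' @export
build_report <- function(keys, roles, libtypes, similarity = NULL,
                         share = NULL, carryover = NULL) {
  sample_of <- function(key) sub("_(DNA|RNA)$", "", key)
  samples <- unique(sample_of(keys))
  rows <- lapply(samples, function(s) {
    my_keys <- keys[sample_of(keys) == s]
    role <- unname(roles[my_keys[1]])
    evidence <- character(0)

    sim_flag <- FALSE
    if (!is.null(similarity)) {
      hit <- similarity[similarity$sample %in% my_keys & similarity$flagged, ]
      if (nrow(hit)) {
        sim_flag <- TRUE
        evidence <- c(evidence, sprintf(
          "abundance: %s (%s)", hit$sample, hit$annotation))
      }
    }

    share_flag <- FALSE
    if (!is.null(share)) {
      other <- function(a, b) ifelse(sample_of(a) == s, b, a)
      rel <- share[(share$sample_a %in% my_keys |
                      share$sample_b %in% my_keys) &
                     share$verdict == "same-strain", , drop = FALSE]
      rel <- rel[sample_of(other(rel$sample_a, rel$sample_b)) != s, ,
                 drop = FALSE]
      if (nrow(rel)) {
        share_flag <- TRUE
        partners <- unique(sample_of(other(rel$sample_a, rel$sample_b)))
        evidence <- c(evidence, sprintf(
          "strains: same %s strain as %s (agreement >= %.2f over >= %d sites)",
          paste(unique(rel$reference), collapse = "/"),
          paste(partners, collapse = ","),
          min(rel$agreement), min(rel$m)))
      }
    }

    dna_flag <- FALSE
    if (!is.null(carryover)) {
      hit <- carryover[carryover$sample %in% my_keys & carryover$verdict, ,
                       drop = FALSE]
      if (nrow(hit)) {
        dna_flag <- TRUE
        evidence <- c(evidence, sprintf(
          "rnacheck: %s on %s, delta_hat=%.3f (w=%d of n=%d)",
          hit$sample, hit$reference, hit$delta_hat, hit$w, hit$n))
      }
    }

    data.frame(sample = s, role = role,
               flag_control_similarity = sim_flag,
               flag_strain_sharing = share_flag,
               flag_dna_carryover = dna_flag,
               suspect = sim_flag || share_flag || dna_flag,
               evidence = paste(evidence, collapse = " | "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("verdict_report", class(out))
  out
}

#' @export
print.verdict_report <- function(x, ...) {
  cat("<verdict_report>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s [%s]: %s\n", x$sample[i], x$role[i],
                if (x$suspect[i]) "SUSPECT CONTAMINATION" else "no evidence"))
    if (!is.null(x$evidence) && nzchar(x$evidence[i])) {
      for (e in strsplit(x$evidence[i], " \\| ")[[1]]) {
        cat(sprintf("    - %s\n", e))
      }
    }
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  qc <- do.call(rbind, Map(function(key, s) cbind(sample = key, s),
                           names(result$qc_summaries), result$qc_summaries))
  write_tsv(qc, file.path(outdir, "qc_summary.tsv"))
  counts <- do.call(rbind, Map(function(key, a)
    cbind(sample = key, a$counts), names(result$assignments),
    result$assignments))
  write_tsv(counts, file.path(outdir, "assignment_counts.tsv"))
  write_tsv(result$accounting, file.path(outdir, "accounting.tsv"))
  write_tsv(result$profiles, file.path(outdir, "abundance.tsv"))
  if (!is.null(result$similarity)) {
    write_tsv(result$similarity, file.path(outdir, "control_similarity.tsv"))
  }
  if (!is.null(result$filter_report)) {
    write_tsv(result$filter_report, file.path(outdir, "control_filter.tsv"))
  }
  if (!is.null(result$share)) {
    write_tsv(result$share, file.path(outdir, "strain_share.tsv"))
  }
  if (!is.null(result$mixtures)) {
    write_tsv(result$mixtures, file.path(outdir, "mixtures.tsv"))
  }
  if (!is.null(result$ani)) {
    write_tsv(result$ani, file.path(outdir, "ani.tsv"))
  }
  if (!is.null(result$carryover)) {
    write_tsv(result$carryover, file.path(outdir, "dna_carryover.tsv"))
  }
  write_tsv(result$report, file.path(outdir, "verdict_report.tsv"))
  invisible(outdir)
}
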