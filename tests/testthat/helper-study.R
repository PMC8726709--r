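# The two end-to-end study runs (contaminated and independent layouts)
# are shared by several test files; cache them for the session.

.study_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(contaminated = TRUE, seed = 42) {
  key <- sprintf("run_%s_%d", contaminated, seed)
  if (is.null(.study_cache[[key]])) {
    study <- study_design_default(seed = seed, contaminated = contaminated)
    .study_cache[[key]] <- list(study = study,
                                result = run_pipeline(study))
  }
  .study_cache[[key]]
}

# A small two-specimen study for fast plumbing tests.
small_study <- function(seed = 7, contaminated = TRUE, n_reads = 1500L) {
  study_design_default(seed = seed, contaminated = contaminated,
                       n_specimens = 2L, n_reads = n_reads)
}
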