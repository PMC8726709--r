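test_that("generate_genome respects length, determinism and GC content", {
  g <- generate_genome(5386, gc = 0.45, seed = 1)
  expect_equal(nchar(g$sequence), 5386)
  expect_false(grepl("[^ACGT]", g$sequence))

  g2 <- generate_genome(5386, gc = 0.45, seed = 1)
  expect_identical(g$sequence, g2$sequence)

  # empirical GC within 3 SD of the binomial expectation
  g3 <- generate_genome(10000, gc = 0.5, seed = 7)
  gc_count <- sum(strsplit(g3$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_count - 5000), 3 * sqrt(10000 * 0.25))

  expect_error(generate_genome(0, gc = 0.5, seed = 1), "positive|non-negative")
  expect_error(generate_genome(100, gc = 1.2, seed = 1), "gc")
})

test_that("derive_strain plants exactly n substitutions and records them", {
  parent <- generate_genome(10000, seed = 3)

  s0 <- derive_strain(parent, 0, seed = 1)
  expect_identical(s0$genome$sequence, parent$sequence)
  expect_equal(nrow(s0$truth), 0)

  s <- derive_strain(parent, 50, seed = 11)
  hamming <- sum(strsplit(parent$sequence, "")[[1]] !=
                   strsplit(s$genome$sequence, "")[[1]])
  expect_equal(hamming, 50)
  expect_equal(nrow(s$truth), 50)
  expect_false(anyDuplicated(s$truth$pos) > 0)
  expect_true(all(s$truth$alt != s$truth$ref))
  # ref alleles match the parent at each recorded position
  expect_identical(substring(parent$sequence, s$truth$pos + 1,
                             s$truth$pos + 1), s$truth$ref)

  # replaying the truth table onto the parent reproduces the strain
  replayed <- apply_strain_truth(parent, s$truth)
  expect_identical(replayed$sequence, s$genome$sequence)

  expect_error(derive_strain(parent, 10001, seed = 1), "exceeds")
})

test_that("simulate_sample draws multinomial source counts and i.i.d. errors", {
  a <- generate_genome(8000, seed = 21, name = "a")
  b <- generate_genome(6000, seed = 22, name = "b")
  panel <- list(a = a, b = b)

  d <- sample_design("s1", "DNA", "specimen",
                     data.frame(id = c("a", "b"), weight = c(0.9, 0.1)),
                     n_reads = 10000, read_length = 100,
                     error_rate = 0, seed = 5)
  sim <- simulate_sample(d, panel)
  expect_equal(nrow(sim$reads), 10000)
  expect_identical(sim$reads$read_id, sim$truth$read_id)
  counts <- table(sim$truth$source)
  expect_lt(abs(counts[["a"]] - 9000), 3 * sqrt(10000 * 0.9 * 0.1))

  # mismatches against the source genome recover the error rate
  d2 <- sample_design("s2", "DNA", "specimen",
                      data.frame(id = "a", weight = 1),
                      n_reads = 1000, read_length = 100,
                      error_rate = 0.01, seed = 6)
  sim2 <- simulate_sample(d2, panel)
  truth_seq <- substring(a$sequence, sim2$truth$position + 1,
                         sim2$truth$position + 100)
  mm <- sum(mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, sim2$reads$seq, truth_seq))
  expected <- 1000 * 100 * 0.01
  expect_lt(abs(mm - expected), 3 * sqrt(expected))
})

test_that("RNA reads respect transcript models and the carryover fraction", {
  g <- generate_genome(10000, seed = 31, name = "g")
  model <- transcript_model("g", data.frame(start = c(2000, 6000),
                                            end = c(4000, 9000)), 10000)
  nt <- non_transcribed_intervals(model)
  expect_equal(nt, data.frame(start = c(0L, 4000L, 9000L),
                              end = c(2000L, 6000L, 10000L)))

  d0 <- sample_design("rna0", "RNA", "specimen",
                      data.frame(id = "g", weight = 1), n_reads = 2000,
                      read_length = 100, error_rate = 0,
                      dna_carryover = 0, seed = 8)
  sim0 <- simulate_sample(d0, list(g = g), list(g = model))
  expect_true(all(!sim0$truth$is_dna_derived))
  # every read wholly within a transcribed interval
  s <- sim0$truth$position
  inside <- (s >= 2000 & s + 100 <= 4000) | (s >= 6000 & s + 100 <= 9000)
  expect_true(all(inside))

  d3 <- sample_design("rna3", "RNA", "specimen",
                      data.frame(id = "g", weight = 1), n_reads = 5000,
                      read_length = 100, error_rate = 0,
                      dna_carryover = 0.3, seed = 9)
  sim3 <- simulate_sample(d3, list(g = g), list(g = model))
  frac <- mean(sim3$truth$is_dna_derived)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))

  # configuration errors
  expect_error(simulate_sample(d0, list(g = g), list()), "transcript model",
               class = "contamtrace_config_error")
  d_long <- sample_design("x", "DNA", "specimen",
                          data.frame(id = "g", weight = 1), n_reads = 10,
                          read_length = 20000, seed = 1)
  expect_error(simulate_sample(d_long, list(g = g)), "read length")
})

test_that("build_study writes a complete, deterministic 16-library layout", {
  study <- small_study(seed = 5, n_reads = 300L)
  out1 <- file.path(tempdir(), "study1")
  out2 <- file.path(tempdir(), "study2")
  sheet <- build_study(study, out1)
  build_study(study, out2)

  # 2 specimens x 2 + 2 controls x 2 = 8 libraries here; the default
  # 6-specimen layout scales to 16
  expect_equal(nrow(sheet), 8)
  expect_true(all(file.exists(sheet$fastq_path)))
  full <- study_design_default(seed = 1)
  expect_equal(length(full$designs), 16)

  # determinism: identical seeds give byte-identical FASTQ
  for (f in basename(sheet$fastq_path)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # truth tables cover every read id exactly once
  for (key in c("C1_DNA", "N_RNA")) {
    truth <- read.table(file.path(out1, paste0(key, ".truth.tsv")),
                        header = TRUE, sep = "\t")
    reads <- read_fastq(file.path(out1, paste0(key, ".fastq")))
    expect_setequal(truth$read_id, reads$read_id)
    expect_equal(anyDuplicated(truth$read_id), 0)
  }

  # negative control contains only contaminant + spike-in sources
  truth_n <- read.table(file.path(out1, "N_DNA.truth.tsv"),
                        header = TRUE, sep = "\t")
  expect_true(all(truth_n$source %in%
                    c("human", "ecoli_contam", "cmar", "phix_spike")))
  unlink(c(out1, out2), recursive = TRUE)
})
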