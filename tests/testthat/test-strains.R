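# Simulate a pure (or mixed) sample from strain genomes and return the
# pileup against the parent reference, bypassing the mapper (positions
# come from the truth table).
pileup_from_strains <- function(parent, strains, weights, coverage,
                                error_rate = 0.001, seed = 1) {
  G <- nchar(parent$sequence)
  L <- 100L
  n <- as.integer(round(coverage * G / L))
  panel <- setNames(strains, vapply(strains, function(g) g$name, character(1)))
  d <- sample_design("mix", "DNA", "specimen",
                     data.frame(id = names(panel), weight = weights),
                     n_reads = n, read_length = L, error_rate = error_rate,
                     seed = seed)
  sim <- simulate_sample(d, panel)
  aln <- alignments_from_truth(sim, names(panel), parent$name)
  build_pileup(aln, parent)
}

test_that("pileups tally every aligned base once", {
  g <- genome("ref", strrep("ACGT", 50))  # 200 bp

  one <- data.frame(read_id = "r1", reference = "ref", start = 10L,
                    strand = "+", aligned_length = 20L,
                    seq = substr(g$sequence, 11, 30))
  pu <- build_pileup(one, g)
  expect_equal(pu$depth[11:30], rep(1L, 20))
  expect_equal(sum(pu$depth), 20)
  # the reference base carries the single count at each covered position
  expect_equal(unname(pu$counts["A", 13]), 1L)  # position 13 (1-based) is A

  # two overlapping reads disagreeing at one position
  s2 <- substr(g$sequence, 11, 30)
  substr(s2, 5, 5) <- "T"  # position 15 is G in the reference
  two <- rbind(one, data.frame(read_id = "r2", reference = "ref",
                               start = 10L, strand = "+",
                               aligned_length = 20L, seq = s2))
  pu2 <- build_pileup(two, g)
  expect_equal(pu2$depth[15], 2L)
  expect_equal(unname(pu2$counts["G", 15]), 1L)
  expect_equal(unname(pu2$counts["T", 15]), 1L)

  # uniform sampling: mean depth equals n * L / G exactly
  parent <- generate_genome(5000, seed = 60, name = "p")
  pu3 <- pileup_from_strains(parent, list(parent), 1, coverage = 20,
                             error_rate = 0, seed = 2)
  expect_equal(mean(pu3$depth), 20, tolerance = 1e-9)

  bad <- data.frame(read_id = "r", reference = "ref", start = 190L,
                    strand = "+", aligned_length = 20L, seq = strrep("A", 20))
  expect_error(build_pileup(bad, g), "bounds")
})

test_that("SNV calling recovers planted variants at 20x with 0.1% error", {
  parent <- generate_genome(5000, seed = 61, name = "p")
  s <- derive_strain(parent, 50, seed = 62)
  pu <- pileup_from_strains(parent, list(s$genome), 1, coverage = 20,
                            seed = 3)
  prof <- call_snvs(pu, parent, fcons = 0.8, cmin = 5)
  called <- prof$variants$pos
  truth <- s$truth$pos
  recall <- length(intersect(called, truth)) / length(truth)
  precision <- if (length(called)) {
    length(intersect(called, truth)) / length(called)
  } else 0
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # called alleles match the planted ones
  hit <- prof$variants[prof$variants$pos %in% truth, ]
  expect_identical(hit$alt,
                   s$truth$alt[match(hit$pos, s$truth$pos)])

  # error-free reads from the reference itself: no variants
  pu0 <- pileup_from_strains(parent, list(parent), 1, coverage = 20,
                             error_rate = 0, seed = 4)
  expect_equal(nrow(call_snvs(pu0, parent)$variants), 0)

  # depth 1 everywhere with cmin 5: nothing callable
  thin <- pileup_from_strains(parent, list(parent), 1, coverage = 1,
                              error_rate = 0, seed = 5)
  expect_equal(sum(call_snvs(thin, parent, cmin = 5)$callable &
                     thin$depth >= 1), sum(thin$depth >= 5))

  expect_error(call_snvs(pu, parent, fcons = 0.5), "exceed")
})

test_that("share_score separates shared from distinct strains symmetrically", {
  parent <- generate_genome(5000, seed = 63, name = "p")
  a <- derive_strain(parent, 50, seed = 64)$genome
  b <- derive_strain(parent, 50, seed = 65)$genome

  prof <- function(strain, seed) {
    pu <- pileup_from_strains(parent, list(strain), 1, coverage = 20,
                              seed = seed)
    call_snvs(pu, parent, sample_id = paste0(strain$name, seed))
  }
  a1 <- prof(a, 10); a2 <- prof(a, 11); b1 <- prof(b, 12)

  # identity
  self <- share_score(a1, a1)
  expect_equal(self$agreement, 1.0)
  expect_equal(self$verdict, "same-strain")

  # same strain, independent read sets
  expect_equal(share_score(a1, a2)$verdict, "same-strain")
  # distinct strains
  expect_equal(share_score(a1, b1)$verdict, "distinct")

  # symmetry
  ab <- share_score(a1, b1); ba <- share_score(b1, a1)
  expect_equal(ab$m, ba$m)
  expect_equal(ab$agreement, ba$agreement)
  expect_equal(ab$verdict, ba$verdict)

  # disjoint callable regions: insufficient data
  half <- length(a1$callable) %/% 2
  a_left <- a1; a_left$callable[seq_len(half)] <- FALSE
  a_right <- a2; a_right$callable[(half + 1):length(a2$callable)] <- FALSE
  expect_equal(share_score(a_left, a_right)$verdict, "insufficient-data")

  other <- call_snvs(build_pileup(empty_aln(), genome("q", strrep("ACGT", 25))),
                     genome("q", strrep("ACGT", 25)), sample_id = "q")
  expect_error(share_score(a1, other), "references")
})

test_that("mixture detection separates pure samples from 70:30 mixes", {
  parent <- generate_genome(5000, seed = 66, name = "p")
  a <- derive_strain(parent, 40, seed = 67)$genome

  pure <- pileup_from_strains(parent, list(a), 1, coverage = 50, seed = 20)
  expect_equal(detect_mixture(pure, sample_id = "pure")$verdict, "single")

  mix <- pileup_from_strains(parent, list(parent, a), c(0.7, 0.3),
                             coverage = 50, seed = 21)
  call <- detect_mixture(mix, sample_id = "mix")
  expect_equal(call$verdict, "mixture")
  expect_equal(call$mean_minor_freq, 0.3, tolerance = 0.07)
  expect_gte(call$n_sites, 30)

  nothing <- build_pileup(empty_aln(), parent)
  expect_equal(detect_mixture(nothing)$verdict, "insufficient-data")
})

test_that("consensus ANI tracks planted divergence", {
  parent <- generate_genome(10000, seed = 68, name = "p")

  # error-free reads from the reference: ANI exactly 100
  pu0 <- pileup_from_strains(parent, list(parent), 1, coverage = 30,
                             error_rate = 0, seed = 30)
  expect_equal(consensus_ani(pu0, parent)$ani, 100.0)

  # 10 SNVs on 10 kb with full callability (error-free 5x tiling of the
  # whole strain sequence): ANI (10000 - 10) / 10000 = 99.9 exactly
  tile_pileup <- function(strain) {
    aln <- data.frame(read_id = paste0("t", 1:5), reference = "p",
                      start = 0L, strand = "+", aligned_length = 10000L,
                      seq = strain$sequence, stringsAsFactors = FALSE)
    build_pileup(aln, parent)
  }
  s10 <- derive_strain(parent, 10, seed = 69)$genome
  r10 <- consensus_ani(tile_pileup(s10), parent)
  expect_equal(r10$compared, 10000)
  expect_equal(r10$ani, 99.9)

  # non-increasing in planted SNV count
  s50 <- derive_strain(parent, 50, seed = 70)$genome
  expect_lte(consensus_ani(tile_pileup(s50), parent)$ani, r10$ani)

  # no coverage: insufficient data, not an exception
  none <- consensus_ani(build_pileup(empty_aln(), parent), parent)
  expect_equal(none$verdict, "insufficient-data")
  expect_true(is.na(none$ani))
})
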