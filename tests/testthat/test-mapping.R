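test_that("map_read finds exact and near-exact loci with correct identity", {
  g <- generate_genome(2000, seed = 50, name = "ref")

  read <- substr(g$sequence, 301, 400)
  hit <- map_read(read, g)
  expect_equal(hit$start, 300)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$strand, "+")

  # two substitutions: identity 0.98, same locus as the exhaustive oracle
  chars <- strsplit(read, "")[[1]]
  chars[10] <- setdiff(c("A", "C", "G", "T"), chars[10])[1]
  chars[60] <- setdiff(c("A", "C", "G", "T"), chars[60])[1]
  read2 <- paste(chars, collapse = "")
  hit2 <- map_read(read2, g, min_identity = 0.9)
  expect_equal(hit2$identity, 0.98)
  orc <- oracle_map(read2, g$sequence)
  expect_equal(hit2$start, orc$start)
  expect_equal(hit2$mismatches, orc$mismatches)

  # reverse-complement reads map to the forward locus on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hit3 <- map_read(rc, g)
  expect_equal(hit3$start, 300)
  expect_equal(hit3$strand, "-")
  expect_equal(hit3$seq, read)  # stored in reference orientation

  # a random read sharing no k-mer: no hit
  set.seed(1)
  expect_null(map_read(random_dna(100), g))

  # reads shorter than the seed yield no hit, with a warning
  expect_warning(res <- map_read(substr(read, 1, 15), g), "shorter")
  expect_null(res)
})

test_that("mapper agrees with the exhaustive all-offset scorer on 500 reads", {
  set.seed(123)
  genomes <- lapply(1:3, function(i) random_dna(2000))
  discrepancies <- 0L
  for (i in 1:500) {
    gseq <- genomes[[(i %% 3) + 1]]
    kind <- i %% 4
    r <- if (kind == 0) {
      list(seq = random_dna(100))  # unrelated read
    } else {
      draw_read(gseq, sample(70:120, 1),
                error_rate = if (kind == 1) 0 else 0.005,
                revcomp = kind == 3)
    }
    hit <- map_read(r$seq, gseq, min_identity = 0.9)
    orc <- oracle_map(r$seq, gseq, min_identity = 0.9)
    agree <- if (is.null(hit) || is.null(orc)) {
      is.null(hit) && is.null(orc)
    } else {
      hit$start == orc$start && hit$strand == orc$strand &&
        hit$mismatches == orc$mismatches
    }
    if (!agree) discrepancies <- discrepancies + 1L
  }
  expect_equal(discrepancies, 0L)
})

test_that("iterative assignment follows panel order and partitions reads", {
  set.seed(7)
  block <- random_dna(150)
  g1 <- genome("g1", paste0(random_dna(400), block, random_dna(400)))
  g2 <- genome("g2", random_dna(1000))
  g3 <- genome("g3", random_dna(1000))
  g4 <- genome("g4", random_dna(1000))
  g5 <- genome("g5", paste0(random_dna(200), block, random_dna(600)))
  panel <- reference_panel(list(g1, g2, g3, g4, g5))

  reads <- data.frame(
    read_id = c("only3", "both15", "nowhere"),
    seq = c(substr(g3$sequence, 101, 200),  # unique to member 3
            substr(block, 11, 110),          # present in members 1 and 5
            random_dna(100)),
    qual = strrep("I", 100), stringsAsFactors = FALSE)

  at <- iterative_assign(reads, panel)
  ass <- setNames(at$assignments$reference, at$assignments$read_id)
  expect_equal(unname(ass["only3"]), "g3")
  expect_equal(unname(ass["both15"]), "g1")  # order precedence
  expect_equal(unname(ass["nowhere"]), "unassigned")
  expect_equal(sum(at$counts$reads), nrow(reads))

  # permuting the panel moves only multi-mappable reads
  panel_rev <- reference_panel(list(g5, g4, g3, g2, g1))
  at2 <- iterative_assign(reads, panel_rev)
  ass2 <- setNames(at2$assignments$reference, at2$assignments$read_id)
  expect_equal(unname(ass2["only3"]), "g3")
  expect_equal(unname(ass2["both15"]), "g5")
  expect_equal(unname(ass2["nowhere"]), "unassigned")

  # empty read set: empty table, not an error
  at0 <- iterative_assign(reads[0, ], panel)
  expect_equal(at0$n_input, 0)
  expect_equal(sum(at0$counts$reads), 0)
})

test_that("competitive assignment recovers true sources on simulated reads", {
  study <- small_study(seed = 31, n_reads = 2000L)
  sim <- simulate_study(study)
  lib <- sim$libraries[["C1_DNA"]]
  at <- iterative_assign(lib$reads, reference_panel(sim$panel))

  # conservation
  expect_equal(sum(at$counts$reads), nrow(lib$reads))

  # accuracy vs the truth table: strains must land on their parent genome
  parent_of <- c(host = "host", human = "human", ecoli = "ecoli",
                 cmar = "cmar", phix = "phix", ecoli_contam = "ecoli",
                 ecoli_lab = "ecoli", phix_spike = "phix")
  truth_ref <- parent_of[lib$truth$source]
  assigned <- setNames(at$assignments$reference, at$assignments$read_id)
  acc <- mean(assigned[lib$truth$read_id] == truth_ref)
  expect_gte(acc, 0.99)
})

test_that("SAM export/import round-trips coordinates, strand and ids", {
  g <- generate_genome(3000, seed = 77, name = "ref")
  set.seed(5)
  reads <- data.frame(
    read_id = paste0("r", 1:40),
    seq = vapply(1:40, function(i) {
      draw_read(g$sequence, 100, error_rate = 0.005, revcomp = i %% 2 == 0)$seq
    }, character(1)),
    qual = strrep("I", 100), stringsAsFactors = FALSE)
  aln <- map_reads(reads, g)
  expect_gt(nrow(aln), 30)

  sam <- tempfile(fileext = ".sam")
  export_alignments(aln, "ref", 3000, sam, reads = reads)

  # SAM is 1-based: POS on disk is exactly start + 1
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, character(1), 4))
  expect_equal(sort(pos), sort(aln$start + 1L))

  imp <- import_alignments(sam, "ref")$alignments
  key <- function(df) df[order(df$read_id), c("read_id", "start", "strand")]
  expect_equal(key(imp), key(aln[, c("read_id", "start", "strand")]),
               ignore_attr = TRUE)
  # sequences come back in reference orientation
  expect_identical(imp$seq[order(imp$read_id)], aln$seq[order(aln$read_id)])

  expect_error(import_alignments(sam, "missing_ref"),
               class = "contamtrace_config_error")
})
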