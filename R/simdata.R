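#' Construct a genome object
#'
#' @param name Genome identifier.
#' @param sequence Nucleotide string over A/C/G/T.
#' @param circular Logical flag. Circular genomes are still simulated
#'   linearly (no origin-spanning reads); the flag is descriptive.
#' @return An object of class `genome`.
#' @export
genome <- function(name, sequence, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("genome length must be > 0", call. = FALSE)
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence restricted to the alphabet A/C/G/T", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp%s\n", x$name,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with the given GC content (G and C
#' equiprobable, likewise A and T). Deterministic for a fixed seed.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param name Genome identifier.
#' @param circular Logical, see [genome()].
#' @return A `genome` object.
#' @examples
#' g <- generate_genome(5386, gc = 0.45, seed = 1, name = "phiX_like")
#' nchar(g$sequence)
#' @export
generate_genome <- function(length, gc = 0.5, seed = NULL,
                            name = "genome", circular = FALSE) {
  stopifnot_scalar_count(length, "length")
  if (length < 1) stop("genome length must be positive", call. = FALSE)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("gc must be strictly between 0 and 1", call. = FALSE)
  }
  bases <- with_seed(seed, sample(c("A", "C", "G", "T"), length,
                                  replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2,
                                           gc / 2, (1 - gc) / 2)))
  genome(name, paste(bases, collapse = ""), circular = circular)
}

#' Derive a strain by planting substitution variants
#'
#' Plants `n_snvs` single-nucleotide substitutions at positions drawn
#' uniformly without replacement; no indels are introduced. The returned
#' truth table records every change (0-based positions) so downstream
#' SNV calls can be scored against it.
#'
#' @param parent A `genome` object.
#' @param n_snvs Number of substitutions (<= parent length).
#' @param seed Integer seed.
#' @param name Name for the derived strain (default `<parent>_strain`).
#' @return A list with `genome` (the derived `genome`) and `truth`
#'   (data frame `pos`, `ref`, `alt`; `pos` 0-based).
#' @export
derive_strain <- function(parent, n_snvs, seed = NULL, name = NULL) {
  stopifnot(inherits(parent, "genome"))
  stopifnot_scalar_count(n_snvs, "n_snvs")
  glen <- nchar(parent$sequence)
  if (n_snvs > glen) stop("n_snvs exceeds genome length", call. = FALSE)
  if (is.null(name)) name <- paste0(parent$name, "_strain")
  if (n_snvs == 0) {
    return(list(genome = genome(name, parent$sequence, parent$circular),
                truth = data.frame(pos = integer(0), ref = character(0),
                                   alt = character(0),
                                   stringsAsFactors = FALSE)))
  }
  res <- with_seed(seed, {
    pos <- sort(sample.int(glen, n_snvs))            # 1-based here
    ref <- substring(parent$sequence, pos, pos)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1), USE.NAMES = FALSE)
    list(pos = pos, ref = ref, alt = alt)
  })
  seq_chars <- strsplit(parent$sequence, "")[[1]]
  seq_chars[res$pos] <- res$alt
  list(genome = genome(name, paste(seq_chars, collapse = ""),
                       parent$circular),
       truth = data.frame(pos = res$pos - 1L, ref = res$ref, alt = res$alt,
                          stringsAsFactors = FALSE))
}

#' Apply a strain truth table to a parent genome
#'
#' Replays recorded substitutions; useful as a round-trip check that a
#' truth table fully describes a derived strain.
#'
#' @param parent A `genome` object.
#' @param truth Truth table from [derive_strain()].
#' @param name Name for the reconstructed genome.
#' @return A `genome` object.
#' @export
apply_strain_truth <- function(parent, truth, name = "replayed") {
  seq_chars <- strsplit(parent$sequence, "")[[1]]
  if (nrow(truth)) {
    if (any(seq_chars[truth$pos + 1L] != truth$ref)) {
      stop("truth table reference alleles do not match the parent genome",
           call. = FALSE)
    }
    seq_chars[truth$pos + 1L] <- truth$alt
  }
  genome(name, paste(seq_chars, collapse = ""), parent$circular)
}

#' Define a transcript model
#'
#' Transcribed intervals are 0-based, half-open, must be sorted,
#' non-overlapping and within genome bounds. Their complement defines
#' the non-transcribed regions used by the DNA-carryover test.
#'
#' @param genome_name Name of the genome the intervals refer to.
#' @param intervals Data frame with columns `start`, `end`.
#' @param genome_length Genome length, for bounds checking and
#'   complement computation.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(genome_name, intervals, genome_length) {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  intervals <- intervals[order(intervals$start), c("start", "end")]
  if (nrow(intervals)) {
    if (any(intervals$start < 0) || any(intervals$end > genome_length) ||
        any(intervals$end <= intervals$start)) {
      stop("transcribed intervals must be non-empty and within genome bounds",
           call. = FALSE)
    }
    if (nrow(intervals) > 1 &&
        any(intervals$start[-1] < intervals$end[-nrow(intervals)])) {
      stop("transcribed intervals must be non-overlapping", call. = FALSE)
    }
  }
  structure(list(genome = genome_name, intervals = intervals,
                 genome_length = as.integer(genome_length)),
            class = "transcript_model")
}

#' Non-transcribed complement of a transcript model
#'
#' @param model A `transcript_model`.
#' @return Data frame of 0-based half-open intervals covering the
#'   non-transcribed part of the genome.
#' @export
non_transcribed_intervals <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  tx <- IRanges::IRanges(start = model$intervals$start + 1L,
                         end = model$intervals$end)
  gaps <- IRanges::gaps(IRanges::reduce(tx), start = 1L,
                        end = model$genome_length)
  data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
             stringsAsFactors = FALSE)
}

#' Describe one sequencing library to simulate
#'
#' @param sample_id Sample identifier.
#' @param library `"DNA"` or `"RNA"`.
#' @param role `"specimen"`, `"negative_control"` or
#'   `"positive_control"`.
#' @param sources Data frame with columns `id` (genome/strain name) and
#'   `weight` (read-count proportion; non-negative, summing to 1).
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution error rate.
#' @param base_quality Phred score assigned to called bases (default 35).
#' @param tail_len If positive, reads selected for tail degradation end
#'   in `tail_len` bases whose quality drops linearly to Q2, to exercise
#'   quality trimming.
#' @param tail_frac Fraction of reads given a degraded tail.
#' @param dna_carryover For RNA libraries, the fraction of reads drawn
#'   uniformly from the whole genome (DNA template carryover) instead of
#'   from transcribed intervals. Fixed at 1 for DNA libraries.
#' @param seed Integer seed.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(sample_id, library = c("DNA", "RNA"),
                          role = c("specimen", "negative_control",
                                   "positive_control"),
                          sources, n_reads, read_length = 100L,
                          error_rate = 0.001, base_quality = 35L,
                          tail_len = 0L, tail_frac = 0, dna_carryover = 0,
                          seed = NULL) {
  library <- match.arg(library)
  role <- match.arg(role)
  stopifnot(is.data.frame(sources), all(c("id", "weight") %in% names(sources)))
  if (any(sources$weight < 0) || abs(sum(sources$weight) - 1) > 1e-8) {
    stop("source weights must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot_scalar_count(n_reads, "n_reads")
  if (library == "DNA") dna_carryover <- 1
  if (dna_carryover < 0 || dna_carryover > 1) {
    stop("dna_carryover must lie in [0, 1]", call. = FALSE)
  }
  structure(list(sample_id = sample_id, library = library, role = role,
                 sources = sources, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 base_quality = as.integer(base_quality),
                 tail_len = as.integer(tail_len), tail_frac = tail_frac,
                 dna_carryover = dna_carryover, seed = seed),
            class = "sample_design")
}

# Quality string for one read: constant base quality with an optional
# linearly degraded tail down to Q2 (Sanger Phred+33).
quality_string <- function(len, base_q, tail_len) {
  q <- rep(base_q, len)
  if (tail_len > 0) {
    t <- min(tail_len, len)
    q[(len - t + 1):len] <- round(seq(base_q, 2, length.out = t))
  }
  intToUtf8(pmin(q, 93L) + 33L)
}

# Sample a start for an RNA-derived read: an interval is chosen with
# probability proportional to its eligible width, then the start is
# uniform within it, so the read lies wholly inside a transcribed
# interval.
sample_transcribed_starts <- function(n, model, read_length) {
  iv <- model$intervals
  elig <- pmax(0L, (iv$end - iv$start) - read_length + 1L)
  if (sum(elig) == 0) {
    stop(sprintf(
      "no transcribed interval of '%s' can hold a %d bp read",
      model$genome, read_length), call. = FALSE)
  }
  which_iv <- sample.int(nrow(iv), n, replace = TRUE, prob = elig)
  iv$start[which_iv] + floor(runif(n) * elig[which_iv])
}

#' Simulate one sequencing library
#'
#' Draws per-source read counts from a multinomial with the design
#' weights, samples read positions (uniform over the genome for DNA and
#' carryover reads; wholly within transcribed intervals for RNA-derived
#' reads), injects i.i.d. substitution errors, and emits Sanger-encoded
#' qualities. Every read is recorded in a truth table.
#'
#' @param design A [sample_design()].
#' @param panel Named list of `genome` objects resolving every source id.
#' @param transcripts Named list of [transcript_model()]s (by genome
#'   name), required for RNA libraries.
#' @return A list with `reads` (data frame `read_id`, `seq`, `qual`) and
#'   `truth` (data frame `read_id`, `source`, `position`,
#'   `is_dna_derived`; positions 0-based).
#' @export
simulate_sample <- function(design, panel, transcripts = NULL) {
  stopifnot(inherits(design, "sample_design"))
  src <- design$sources
  missing <- setdiff(src$id, names(panel))
  if (length(missing)) {
    config_error(sprintf("unresolvable source id(s): %s",
                         paste(missing, collapse = ", ")))
  }
  L <- design$read_length
  glens <- vapply(panel[src$id], function(g) nchar(g$sequence), integer(1))
  if (any(L > glens)) {
    stop("read length exceeds the shortest source genome", call. = FALSE)
  }
  if (design$library == "RNA") {
    no_model <- setdiff(src$id, names(transcripts))
    if (length(no_model)) {
      config_error(sprintf("RNA source(s) without a transcript model: %s",
                           paste(no_model, collapse = ", ")))
    }
  }

  with_seed(design$seed, {
    n <- design$n_reads
    counts <- as.integer(rmultinom(1, n, src$weight))
    source_of <- rep(src$id, counts)

    position <- integer(n)
    is_dna <- logical(n)
    offset <- 0L
    for (i in seq_len(nrow(src))) {
      ni <- counts[i]
      if (ni == 0) next
      gid <- src$id[i]
      glen <- glens[i]
      idx <- offset + seq_len(ni)
      if (design$library == "DNA") {
        dna <- rep(TRUE, ni)
      } else {
        dna <- runif(ni) < design$dna_carryover
      }
      pos <- integer(ni)
      n_dna <- sum(dna)
      if (n_dna) pos[dna] <- floor(runif(n_dna) * (glen - L + 1L))
      if (ni - n_dna > 0) {
        pos[!dna] <- sample_transcribed_starts(ni - n_dna,
                                               transcripts[[gid]], L)
      }
      position[idx] <- pos
      is_dna[idx] <- dna
      offset <- offset + ni
    }

    seqs <- substring(
      vapply(panel[source_of], function(g) g$sequence, character(1)),
      position + 1L, position + L)

    # i.i.d. substitution errors at rate e
    n_err <- rbinom(n, L, design$error_rate)
    for (r in which(n_err > 0L)) {
      chars <- strsplit(seqs[r], "")[[1]]
      at <- sample.int(L, n_err[r])
      chars[at] <- vapply(chars[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1), USE.NAMES = FALSE)
      seqs[r] <- paste(chars, collapse = "")
    }

    degraded <- runif(n) < design$tail_frac
    plain_q <- quality_string(L, design$base_quality, 0L)
    tail_q <- quality_string(L, design$base_quality, design$tail_len)
    quals <- ifelse(degraded & design$tail_len > 0L, tail_q, plain_q)

    perm <- sample.int(n)
    read_id <- sprintf("%s_r%06d", design$sample_id, seq_len(n))
    reads <- data.frame(read_id = read_id, seq = seqs[perm],
                        qual = quals[perm], stringsAsFactors = FALSE)
    truth <- data.frame(read_id = read_id, source = source_of[perm],
                        position = position[perm],
                        is_dna_derived = is_dna[perm],
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Default multi-sample study design
#'
#' Builds the synthetic counterpart of a low-biomass fetal-gut
#' sequencing study: six specimens plus one negative and one positive
#' control, each with a DNA and an RNA library (16 libraries). The panel
#' holds five reference genomes in host-first mapping order (host sheep
#' stand-in, human, *E. coli*, *C. marimammalium* and a phiX-like
#' spike-in virus). In the contaminated layout every library shares the
#' same spike-in virus strain and the same contaminant *E. coli* strain,
#' the negative control carries the contaminants at comparable
#' abundance, the positive control mixes the lab strain with the
#' contaminant strain 70:30, and RNA libraries carry a tunable fraction
#' of DNA-derived reads. The independent layout gives every specimen a
#' private *E. coli* strain at high abundance, a near-empty negative
#' control, and no DNA carryover.
#'
#' @param seed Integer seed controlling genomes, strains and reads.
#' @param n_reads Reads per library.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution error rate.
#' @param dna_carryover DNA-derived read fraction for RNA libraries in
#'   the contaminated layout.
#' @param contaminated Logical; `FALSE` yields the independent-strains,
#'   carryover-free layout.
#' @param n_specimens Number of specimens.
#' @param genome_lengths Named integer vector of panel genome lengths.
#' @return A list of class `study_design` with elements `panel` (ordered
#'   named list of reference `genome`s), `sources` (named list of all
#'   simulable genomes, including strains), `transcripts`,
#'   `strain_truth` (named list of truth tables) and `designs` (list of
#'   `sample_design`s).
#' @export
study_design_default <- function(seed = 1, n_reads = 6000L,
                                 read_length = 100L, error_rate = 0.001,
                                 dna_carryover = 0.2, contaminated = TRUE,
                                 n_specimens = 6L,
                                 genome_lengths = c(host = 30000L,
                                                    human = 15000L,
                                                    ecoli = 12000L,
                                                    cmar = 8000L,
                                                    phix = 5386L)) {
  panel <- list()
  for (i in seq_along(genome_lengths)) {
    nm <- names(genome_lengths)[i]
    panel[[nm]] <- generate_genome(genome_lengths[[i]], gc = 0.45,
                                   seed = derive_seed(seed, i), name = nm,
                                   circular = nm == "phix")
  }

  sources <- panel
  strain_truth <- list()

  # Shared spike-in virus strain: present in every library of the
  # contaminated layout.
  # 40 SNVs (~0.7% divergence): enough sites remain inside transcribed
  # regions that RNA libraries keep >= m_min comparable sites
  spike <- derive_strain(panel$phix, 40L, seed = derive_seed(seed, 101),
                         name = "phix_spike")
  sources$phix_spike <- spike$genome
  strain_truth$phix_spike <- spike$truth

  # Contaminant E. coli strain shared across wells, plus the pure lab
  # strain used in the positive control.
  contam <- derive_strain(panel$ecoli, 60L, seed = derive_seed(seed, 102),
                          name = "ecoli_contam")
  sources$ecoli_contam <- contam$genome
  strain_truth$ecoli_contam <- contam$truth
  sources$ecoli_lab <- panel$ecoli  # the reference IS the lab strain
  lab <- list(genome = panel$ecoli)

  # Private strains for the independent layout.
  for (i in seq_len(n_specimens)) {
    nm <- sprintf("ecoli_private_%d", i)
    s <- derive_strain(panel$ecoli, 60L, seed = derive_seed(seed, 200 + i),
                       name = nm)
    sources[[nm]] <- s$genome
    strain_truth[[nm]] <- s$truth
  }

  # Transcript models: ~60-70% of each genome transcribed, leaving a
  # non-transcribed block at the start (the spike-in's stands in for the
  # non-transcribed region around a phage origin of replication).
  transcripts <- list()
  for (nm in names(panel)) {
    G <- genome_lengths[[nm]]
    iv <- data.frame(start = c(round(G * 0.25), round(G * 0.60)),
                     end = c(round(G * 0.50), round(G * 0.95)))
    transcripts[[nm]] <- transcript_model(nm, iv, G)
  }
  # Strains share the parent's coordinates, hence its transcript model.
  transcripts$phix_spike <- transcript_model("phix_spike",
                                             transcripts$phix$intervals,
                                             genome_lengths[["phix"]])
  for (nm in grep("^ecoli_", names(sources), value = TRUE)) {
    transcripts[[nm]] <- transcript_model(nm, transcripts$ecoli$intervals,
                                          genome_lengths[["ecoli"]])
  }

  w <- function(...) {
    x <- c(...)
    data.frame(id = names(x), weight = unname(x) / sum(x),
               stringsAsFactors = FALSE)
  }

  designs <- list()
  k <- 0L
  add <- function(id, library, role, sources_df, delta) {
    k <<- k + 1L
    designs[[length(designs) + 1L]] <<- sample_design(
      sample_id = id, library = library, role = role, sources = sources_df,
      n_reads = n_reads, read_length = read_length, error_rate = error_rate,
      tail_len = 60L, tail_frac = 0.10,
      dna_carryover = if (library == "RNA") delta else 1,
      seed = derive_seed(seed, 1000 + k))
  }

  if (contaminated) {
    for (i in seq_len(n_specimens)) {
      sw <- w(host = 0.60, human = 0.02, ecoli_contam = 0.22,
              cmar = 0.04, phix_spike = 0.12)
      add(sprintf("C%d", i), "DNA", "specimen", sw, dna_carryover)
      add(sprintf("C%d", i), "RNA", "specimen", sw, dna_carryover)
    }
    nw <- w(human = 0.15, ecoli_contam = 0.45, cmar = 0.05,
            phix_spike = 0.35)
    add("N", "DNA", "negative_control", nw, dna_carryover)
    add("N", "RNA", "negative_control", nw, dna_carryover)
    pw <- w(ecoli_lab = 0.63, ecoli_contam = 0.27, phix_spike = 0.10)
    add("P", "DNA", "positive_control", pw, dna_carryover)
    add("P", "RNA", "positive_control", pw, dna_carryover)
  } else {
    for (i in seq_len(n_specimens)) {
      sw <- w(host = 0.80, setNames(0.20, sprintf("ecoli_private_%d", i)))
      add(sprintf("C%d", i), "DNA", "specimen", sw, 0)
      add(sprintf("C%d", i), "RNA", "specimen", sw, 0)
    }
    nw <- w(human = 1)
    add("N", "DNA", "negative_control", nw, 0)
    add("N", "RNA", "negative_control", nw, 0)
    pw <- w(ecoli_lab = 1)
    add("P", "DNA", "positive_control", pw, 0)
    add("P", "RNA", "positive_control", pw, 0)
  }

  structure(list(panel = panel, sources = sources, transcripts = transcripts,
                 strain_truth = strain_truth, designs = designs, seed = seed),
            class = "study_design")
}

#' Simulate every library of a study design in memory
#'
#' @param study A `study_design` (see [study_design_default()]).
#' @return Named list (by `<sample_id>_<library>`) of
#'   [simulate_sample()] results, with the study's `panel`,
#'   `transcripts` and `designs` attached.
#' @export
simulate_study <- function(study) {
  stopifnot(inherits(study, "study_design"))
  libs <- list()
  for (d in study$designs) {
    key <- paste(d$sample_id, d$library, sep = "_")
    if (key %in% names(libs)) {
      config_error(sprintf("duplicate sample id/library: %s", key))
    }
    libs[[key]] <- simulate_sample(d, study$sources, study$transcripts)
  }
  list(libraries = libs, panel = study$panel,
       transcripts = study$transcripts, designs = study$designs)
}

#' Write a simulated study to disk
#'
#' Produces one FASTQ and one truth TSV per library, a FASTA of the
#' reference panel, BED files of transcribed intervals, and a sample
#' sheet (`sample_id`, `library`, `role`, `fastq_path`).
#'
#' @param study A `study_design`.
#' @param outdir Output directory (created if needed).
#' @return The sample sheet data frame, invisibly; files are written
#'   under `outdir`.
#' @export
build_study <- function(study, outdir) {
  sim <- simulate_study(study)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$panel, file.path(outdir, "panel.fasta"))
  for (nm in names(study$transcripts)) {
    m <- study$transcripts[[nm]]
    if (nrow(m$intervals)) {
      write_bed(data.frame(chrom = nm, start = m$intervals$start,
                           end = m$intervals$end),
                file.path(outdir, paste0(nm, ".transcribed.bed")))
    }
  }
  rows <- list()
  for (d in study$designs) {
    key <- paste(d$sample_id, d$library, sep = "_")
    fq <- file.path(outdir, paste0(key, ".fastq"))
    write_fastq(sim$libraries[[key]]$reads, fq)
    write_tsv(sim$libraries[[key]]$truth,
              file.path(outdir, paste0(key, ".truth.tsv")))
    rows[[key]] <- data.frame(sample_id = d$sample_id, library = d$library,
                              role = d$role, fastq_path = fq,
                              stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_tsv(sheet, file.path(outdir, "sample_sheet.tsv"))
  invisible(sheet)
}
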