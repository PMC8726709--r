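---
title: "Contamination forensics for low-biomass sequencing studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contamination forensics for low-biomass sequencing studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contamtrace)
```

## The problem

Low-biomass samples — fetal tissue, placenta, clean-room swabs,
template-free extraction controls — contain so little endogenous
microbial DNA that reagent contamination, sequencing spike-ins and
well-to-well transfer between co-processed samples can dominate the
library. DNA-based detection alone cannot distinguish a genuine
microbiome from this background: the same species list, at similar
relative abundances, is exactly what contamination produces. contamtrace
implements three complementary, quantitative lines of evidence for
deciding between colonization and contamination, together with a
synthetic-data generator that makes the whole inference chain testable
against known truth.

1. **Abundance forensics.** Reads are assigned competitively against an
   ordered reference panel and accounted with explicit denominators; a
   sample whose entire non-host profile sits within a small fold of the
   negative (template-free) control carries no signal that background
   cannot explain.
2. **Strain forensics.** Truly independent biological samples should
   harbour *genomically distinct* strains of a species. Per-sample SNV
   profiles against a reference, pairwise sharing scores, within-sample
   mixture detection and consensus average nucleotide identity (ANI)
   test that expectation; identical strains in nominally independent
   samples (and in controls) indicate well-to-well or reagent transfer.
3. **Template forensics.** RNA libraries should not cover genome regions
   that are never transcribed. Reads mapping wholly inside
   non-transcribed intervals reveal residual genomic DNA, and their
   count converts into an estimated DNA-derived read fraction.

## Competitive (iterative map-and-remove) assignment

Cross-mapping between related references confounds abundance estimates,
so reads are mapped against panel members *in order* (host first, then
other eukaryotes, bacteria, spike-in virus last); a read mapping to
member *i* is removed from the pool before member *i + 1*. Each read is
assigned at most once and the per-reference counts plus the unassigned
remainder always partition the input — an invariant asserted on every
run.

The built-in mapper is a deterministic seed-and-extend aligner:
candidate loci are exact k-mer matches (default `k = 21`) on either
strand, scored by ungapped full-length extension; the best locus is
reported when identity reaches `min_identity` (default 0.90), with ties
broken toward the forward strand, then the lowest coordinate. Indel
alignment is deliberately out of scope — every downstream statistic here
is substitution-based — and `import_alignments()` accepts SAM/BAM from
an external mapper such as BWA for users who prefer one. At most 50
candidate loci (lowest coordinates) are evaluated per read, which keeps
behaviour deterministic on repetitive references. The mapper is
validated in the test suite against an exhaustive all-offset,
both-strand scorer.

## Quality trimming

`run_qc()` reproduces the common sliding-window contract
(`SLIDINGWINDOW:4:20, MINLEN:70`): scan 5'→3' in 4-base windows, clip at
the start of the first window whose mean Phred quality falls below 20,
discard reads shorter than 70 bases after clipping. Two details are
fixed so results are bit-reproducible: trimming clips *at the window
start* (no re-scan of trailing bases — published trimmers differ here,
so counts from other tools may differ slightly), and `min_length` is an
absolute base count, which coincides with "truncated by more than 30%"
only for 100 bp reads. Reads shorter than one window are evaluated as a
single window. Qualities are Sanger Phred+33 (offset configurable).

## Abundance accounting and the negative-control filter

Accounting rows follow the dual-denominator convention of published
read-accounting tables: the host percentage is relative to
quality-retained reads; every other taxon is relative to the *filtered*
(host-depleted) read count; percentages are rounded half away from zero
to one decimal (`percent()`).

`control_filter()` reimplements the `log2FoldChange > 2` contaminant
filter at the taxon level: a taxon is kept iff

$$\log_2\frac{\bar{a} + \varepsilon_s}{c + \varepsilon_c} > 2,$$

i.e. iff its mean specimen abundance exceeds four times the
negative-control abundance (strictly). The original gene-centric
formulation operates on assembled gene catalogues, which this package
deliberately does not reproduce; the taxon-level form keeps the
arithmetic explicit. Because control abundances can be zero, a
pseudocount of one read — converted to the percent scale through each
side's denominator — guards the ratio; the published calculation this
mirrors did not document its handling of zeros, so ours is explicit and
configurable.

`control_similarity_flag()` formalises "detected in similar proportions
in samples and control": a sample is flagged when *every* detected taxon
lies within `kc`-fold (default 4, mirroring the filter's fold) of — or
below — the negative control. A sample with no detected non-host taxa is
flagged with a "no signal above control" annotation.

## Strain-level evidence

`build_pileup()` tallies aligned bases per position;
`call_snvs()` marks a position as a consensus SNV when depth ≥ `cmin`
(default 5) and the best non-reference allele reaches frequency `fcons`
(default 0.8). Positions with depth ≥ `cmin` form the callable mask.

`share_score()` compares two profiles over *comparable* sites —
callable in both samples and variant in at least one — and reports the
fraction with identical major alleles. Verdicts: `same-strain`
(agreement ≥ 0.99 over ≥ `m_min = 10` sites), `distinct`, or
`insufficient-data`. The score is symmetric, and on simulated pairs
with ≥ 30 truth-SNV separation at 20× depth the classification is
error-free across 100 seeds (see the acceptance script).

`detect_mixture()` looks for the signature of two co-occurring strains:
a coherent band of intermediate minor-allele frequencies. A sample is a
`mixture` when at least `site_min = 5` callable sites carry a minor
allele in `[0.2, 0.8]` supported by at least two reads (a singleton read
cannot evidence a mixture; without this guard, depth-5 sites with one
sequencing error masquerade as intermediate sites). The mean and SD of
the in-band frequencies are reported; SD ≤ 0.15 is annotated as
*coherent*, approximating the visual haplotype grouping a genome viewer
would show. Read-level linkage of adjacent shared SNVs is not required —
at typical short-read depths most discriminating sites do not co-occur
on one read.

`consensus_ani()` compares the sample consensus (ties resolved toward
the reference base) against the reference over callable sites. This is
consensus-vs-reference identity, *not* the fragment-based ANI of
assembly-to-assembly tools: the pipeline has mapped reads, not
assembled queries, so the consensus form is the faithful analogue here.
At a 70:30 two-strain mixture the consensus tracks the majority strain,
so a positive control mixing a lab strain with a contaminant still shows
~100% ANI to the lab reference while the mixture call exposes the second
strain.

## DNA carryover in RNA libraries

RNA-derived reads lie within transcribed regions. Under uniform DNA read
starts, the probability that a read of length $L$ falls wholly inside
the non-transcribed interval set (lengths $\ell_i$, genome length $G$)
is

$$E = \frac{\sum_i \max(0, \ell_i - L + 1)}{G - L + 1},$$

so with $w$ such reads among $n$ mapped,
$\hat\delta = \min(1, (w/n)/E)$ estimates the DNA-derived fraction.
Counting only *fully interior* reads is conservative — RNA reads may
legitimately straddle interval boundaries but can never lie wholly
inside the complement — and admits this closed form. A per-base
depth-ratio cross-check (`depth_ratio_nontranscribed()`) is provided. A
reporting floor of $\hat\delta \ge 0.01$ (configurable) prevents single
stray alignments from flagging a library. Transcribed intervals are
user input (BED, 0-based half-open); no biology is hard-coded. At
n = 50,000 reads the estimator recovers $\delta \in \{0, 0.1, 0.3,
0.5, 1\}$ within ±0.05 (acceptance script), and it is monotone in the
true fraction.

## The synthetic study and what it does (and does not) show

`study_design_default()` emulates the structure of a contested
low-biomass fetal-gut study: six specimens plus a negative
(template-free) and a positive control, each sequenced as one DNA and
one RNA library (16 libraries). The reference panel is five genomes in
host-first mapping order — a host stand-in, human, *E. coli*,
*C. marimammalium*, and a phiX-like spike-in virus of exactly 5,386 bp.
In the **contaminated** layout every library carries the same spike-in
virus strain (40 SNVs from the reference — enough that the transcribed
fraction alone keeps RNA libraries above the `m_min` comparable-site
floor) and the same contaminant
*E. coli* strain (60 SNVs); the negative control holds the contaminants
at comparable relative abundance; the positive control mixes the lab
strain (the reference itself) 70:30 with the contaminant strain; RNA
libraries carry a DNA fraction of 0.2. In the **independent** layout
each specimen gets a private *E. coli* strain at high abundance, the
negative control is nearly empty, and carryover is zero.

Conditions were fixed once, as follows. Reads are 100 bp single-end at a
0.1% substitution error rate (Illumina-like); base quality is Q35 with
10% of reads given a 60-base tail decaying linearly to Q2 so that
trimming has real work to do. Libraries hold 6,000 reads against
scaled-down genomes (host 30 kb down to the 5,386 bp virus), sized so
that every reference that feeds the strain stage reaches at least ~10×
depth — the regime the SNV thresholds (`cmin = 5`, `fcons = 0.8`)
need. The source study published no quantitative well-to-well
proportions, so the mixing weights above are this package's choice and
are configurable.

Deliberate simplifications, hence what passing tests do *not* show
about real data: reads are single-end, forward-strand, substitution-only
(no indels, adapters, PCR duplicates or GC bias); circular genomes are
simulated linearly, so coverage ramps down over the last read-length at
genome ends (whole-genome breadth sits just below 100% by construction,
and no origin-spanning reads exist); host fractions are far below the
>99% of real host-dominated libraries, purely to keep per-reference
depth adequate at desk scale. Real-data absolute read counts are not
reproducible by design — they depend on an external mapper's stringency —
only the accounting arithmetic and the qualitative verdicts are.

## Numerical choices and degenerate inputs

* `percent()` rounds half away from zero to one decimal; a zero
  denominator yields 0.0 with a warning.
* Mapper ties: forward strand, then lowest start. Reads shorter than
  `k` are no-hits with a warning.
* Consensus ties in `consensus_ani()` resolve toward the reference
  base (then alphabetically), so zero-information ties do not deflate
  identity.
* Empty inputs return typed empty results or `insufficient-data`
  verdicts, never exceptions: empty FASTQ → zero-count QC summary;
  empty read set → empty assignment table; zero callable sites →
  `insufficient-data` for sharing, mixture and ANI; `n = 0` mapped
  reads → `insufficient-data` carryover.
* Every stochastic stage takes an explicit integer seed; per-library
  seeds are derived from the study seed, and a fixed seed gives
  byte-identical FASTQ and TSV outputs.

## The end-to-end verdict

`run_pipeline()` composes the stages and `build_report()` folds the
three evidence classes into one verdict per sample; a sample is
*suspect* iff at least one evidence line is present, and every line
cites the producing module with its numbers. On the contaminated
default study all six specimens are flagged with all three evidence
classes — the spike-in virus is called `same-strain` across all 16
libraries including both controls, the positive control is called a
two-strain mixture, and the taxon-level fold filter removes every
shared taxon (what the filter *should* have done in the motivating
case). On the independent layout no sample raises any flag. These two
runs, plus the module-level recoveries above, are exactly what
`scripts/acceptance.R` recomputes.

```{r example, eval = FALSE}
study <- study_design_default(seed = 1)
res <- run_pipeline(study, outdir = "run1")
res$report
```

## Known limitations

Taxon-level (not gene-level) filtering; ungapped mapping only; no
phasing or haplotype assembly beyond the frequency-band heuristic; no
strandedness or splice awareness in the RNA check; linear treatment of
circular genomes. Each limitation is either configurable around
(external SAM import) or conservative in direction (interior-read
counting underestimates, never overestimates, carryover).
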