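Package: contamtrace
Title: Contamination Forensics for Low-Biomass Metagenomes and
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether microbial signal in low-biomass
    shotgun sequencing data reflects colonization or contamination.
    Implements ordered competitive (iterative map-and-remove) read
    assignment against a reference panel, negative-control-aware
    abundance accounting and fold-change filtering, strain-level
    single-nucleotide-variant (SNV) profile sharing and within-sample
    strain-mixture detection, consensus average nucleotide identity,
    and a DNA-carryover test for metatranscriptomes based on coverage
    of non-transcribed genome regions. A synthetic-data module
    generates genomes, strains, transcript models and reads with
    machine-readable truth tables so the whole inference chain can be
    validated without access to the original sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
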