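Package: pgxprofiler
Title: WGS-Based Pharmacogenetic Profiling of DPWG Pharmacogenes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacogenetic (PGx) profiling from whole-genome sequencing
    variant calls. Bundles a DPWG-style panel of 45 star-allele defining
    SNVs/indels in 11 pharmacogenes plus the HLA-B*57:01 tag variant and a
    CYP2D6 structural-variant slot; calls per-individual star alleles and
    diplotypes from (g)VCF input, translates diplotypes to metabolizer
    phenotypes and drug-dosing recommendations, and emits a machine-readable
    Medication Safety Card payload. Provides cohort-level pharmacogene
    landscape summaries (relative allele frequencies with inferred wildtype
    alleles, minor-allele-frequency bins, continuity-corrected Wilson
    confidence intervals), a loss-of-function/consensus-damaging-missense
    variant classification cascade, a CYP2D6 diplotype grammar with a
    phase-insensitive concordance scorer for benchmarking structural-variant
    callers against consensus genotypes, and a deterministic synthetic-cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
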