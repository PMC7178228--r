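---
title: "WGS-based pharmacogene profiling: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WGS-based pharmacogene profiling: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxprofiler)
library(dplyr)
```

# The problem

Pre-emptive pharmacogenetic (PGx) testing asks, before a drug is prescribed,
which of a small set of well-characterised variants an individual carries in
the genes that control drug metabolism, transport and targets. Whole-genome
sequencing performed for diagnostic reasons already contains this
information; the work is in extracting it reliably and translating genotypes
into guideline-backed actions. `pgxprofiler` implements that extraction and
translation for a DPWG-style panel: 45 star-allele defining SNVs/indels in 11
pharmacogenes (CYP2B6, CYP2C9, CYP2C19, CYP2D6, CYP3A5, DPYD, F5, SLCO1B1,
TPMT, UGT1A1, VKORC1), the HCP5 rs2395029 variant tagging HLA-B\*57:01, and a
slot for CYP2D6 structural alleles called by external tools. It also
implements the cohort-level view — how much of the observed
pharmacogenetically relevant variation the panel captures — and a scorer for
benchmarking CYP2D6 diplotype callers against consensus reference genotypes.

# Star alleles, diplotypes and phenotypes

A *star allele* is a named haplotype of a pharmacogene; `*1` denotes the
reference (wildtype) haplotype. The bundled panel maps each genomic variant
to its star allele and a *function class* (`no_function`, `decreased`,
`normal`, `increased`, `unknown`). A *diplotype* is the unordered pair of
star alleles an individual carries, and a *metabolizer phenotype*
(PM/IM/NM/RM/UM) is derived from the pair of function classes via a declared
rule table following the DPWG convention: two no-function alleles give PM,
two increased-function alleles give UM, and intermediate combinations grade
between. Carrier-style genes use explicit star-pair rules instead: F5
(Factor V Leiden) and the HCP5 tag report carrier/non-carrier, VKORC1
reports coumarin sensitivity.

Only the PM and UM anchors of this table are fixed by common usage; the
remaining cells are a design choice. We use one generic table for all genes
rather than per-gene activity scores, which flattens some known gene
differences — e.g. CYP2C9 `*2/*2` (decreased + decreased) translates to IM
here although many sources describe `*2` homozygotes as poor metabolizers.
The table ships as an editable TSV (`phenotype_rules.tsv`), so a deployment
can tighten individual genes without code changes. Dose-relevant decisions
in this package are keyed on diplotypes, not phenotypes, so this choice does
not affect dosing output.

Two further conventions deserve a note:

* **CYP2B6 \*6.** The panel genotypes the two component variants c.516G>T
  (`*9`) and c.785A>G (`*4`); when both are present at equal dosage they are
  reported as the `*6` haplotype, following standard genotyping practice.
  This is the one deliberate exception to the trans assumption below.
* **CYP3A5 expressers.** `*1/*1` individuals are CYP3A5 expressers and
  nominally actionable for tacrolimus, but an all-wildtype diplotype is also
  the no-evidence state of the caller. Recommendations therefore fire only
  for diplotypes carrying a detected variant allele: heterozygous expressers
  (`*1/*3`, IM) receive the tacrolimus advisory, `*1/*1` does not. This is a
  deliberate deviation from strictly genotype-triggered guideline behaviour,
  chosen so that reports never act on absence of evidence.

# The trans assumption and its consequences

Short-read WGS leaves panel variants unphased. Whenever two variants are
detected in the same gene, the package assumes they lie **in trans** (on
different haplotypes). This has three visible consequences:

1. **Diplotype calls.** Two heterozygous variants in one gene form a
   two-allele diplotype flagged `ambiguous_phase`. More than two assigned
   alleles cannot be a diploid state: the two highest-impact alleles
   (no function > decreased > increased > normal) are kept and the call is
   flagged `possible_misclassification` — conservative in the direction of
   caution, since the discarded allele can only have made things less
   functional.
2. **Wildtype inference.** At cohort level the number of `*1` alleles is
   inferred as total alleles minus detected variant alleles. If in-cis pairs
   exist this *underestimates* wildtype alleles; when detected alleles exceed
   the total the count floors at zero and the landscape row is flagged
   `overflow` rather than erroring.
3. **Co-occurrence screening.** Because an in-cis novel loss-of-function
   (LOF) variant next to an increased-function allele would invert the
   phenotype interpretation, every gene with two or more relevant variants
   in one individual is reported as a co-occurrence note, and genes
   combining a panel variant with a novel LOF/missense variant additionally
   flag the diplotype call.

Statistical phasing is deliberately out of scope; no genotype is ever
imputed. A panel site with no genotype data yields an explicit unknown
allele (`?`) and phenotype `unknown` — unknown is never silently wildtype.

# Variant classification cascade

Retained sites are classified with precedence **panel match > LOF >
consensus-damaging missense > other**:

* *Panel match* is exact coordinate/allele equality after multi-allelic
  decomposition and indel left-alignment (so the overlapping UGT1A1 `*28` /
  `*37` TA-repeat duplications match regardless of input representation).
* *LOF* covers premature termination (nonsense, frameshift — with or without
  expected nonsense-mediated decay) and canonical ±1–2 bp splice-site SNVs
  predicted to alter splicing. If no splice prediction column is available,
  canonical splice SNVs default to altering, with a warning.
* *Consensus-damaging missense* requires all six predictor verdicts (FATHMM,
  FATHMM-MKL, MutationAssessor, MutationTaster, PolyPhen-2, SIFT) to be
  damaging/deleterious — a strict conjunction; a missing verdict never
  counts as damaging.
* LOF/missense variants in HLA-B are classified `other`
  (reason `hla_excluded`): short-read alignment in the HLA region is too
  ambiguous to trust, which is why the panel carries the HCP5 tag variant
  instead, valid as a HLA-B\*57:01 proxy in European-ancestry populations
  only.

Novelty is `known` when any database flag is set (ClinVar drug response,
HGMD FP/DFP/DM?/DM in drug-response context, PharmGKB), else `novel`. A
database flag can change novelty but never the category. If a panel variant
is also LOF, the panel takes precedence — panel semantics dominate, and the
variant's guideline meaning is better defined than its molecular
consequence.

Site-level filtering happens before classification: non-PASS records and
records with 150-mer mappability below 1.0 are excluded, each with a
machine-readable reason, and retained plus excluded rows always partition
the input. Missing mappability is treated as 1.0 with a warning rather than
silently dropping data.

# Cohort landscape statistics

Relative allele frequencies are computed per gene over all detected DPWG and
LOF/missense alleles plus the inferred wildtype; the per-gene frequencies
sum to one and allele counts are conserved by construction (asserted on
every landscape build). MAF bins follow the printed convention of strict
inequalities (<0.1%, 0.1–5%, >5%); because strict inequalities leave the
boundaries unassigned, this package fixes [0, 0.1%) = rare, [0.1%, 5%] =
low, (5%, 50%] = common. The choice is visible only for counts landing
exactly on a boundary — e.g. a singleton in a 500-genome cohort (1/1000 =
0.1%) is "low", while the same singleton in a 547-genome cohort (1/1094) is
"rare". MAF is always the minor allele, `min(AC, AN−AC)/AN`, because
high-frequency alleles such as CYP3A5\*3 exceed 50% alternate-allele
frequency.

Confidence intervals are 95% Wilson score intervals **with continuity
correction** (Newcombe's method 4) — the interval produced by classic
proportion calculators. The closed form is implemented directly; the test
suite checks it to 1e-6 against an independent numerical solution of the
continuity-corrected score equation and verifies ≥93% empirical coverage
over 2,000 binomial draws at p = 0.01, 0.1 and 0.5 (the interval is
conservative, so coverage at or above nominal is expected).

One tallying convention: a tandem haplotype such as `*68+*4` counts as one
allele (one haplotype = one allele label), noted in output metadata.

# CYP2D6 diplotype grammar and concordance scoring

CYP2D6 structural alleles force a richer diplotype notation:
`*5` (whole-gene deletion), `*2x2` (duplication, also printed `*2×2`),
`*68+*4` (hybrid tandem on one haplotype), and, in consensus genotypes,
parenthesized segments like `(*36)+*10`. The grammar is

```
DIP  := HAP "/" HAP
HAP  := COMP ("+" COMP)*
COMP := ["("] "*" LABEL ["x" N] [")"]
```

Scoring a caller's diplotype against a consensus genotype is
**phase-insensitive multiset comparison**: both sides are expanded to
multisets of allele labels (`xN` contributes N copies), and the call is
correct iff the multisets are equal after applying any per-sample accepted
allele equivalences. Three conventions are fixed by how published
tool-comparison tallies are computed:

* **Parenthesized consensus segments are required**, not optional. This is
  the only reading that reproduces published per-caller tallies — a call of
  `*3/*4` against consensus `*3/(*68)+*4` is incorrect unless the caller
  separately reported the `*68` hybrid — although it diverges from the more
  common reading of parentheses as uncertainty. The parser still records the
  optional annotation for display.
* **Footnote annotations are data.** A hybrid reported alongside a call is
  appended to the call's multiset before comparison; an unassigned
  duplication flag contributes nothing; a caller that produced no phased
  major solution is incorrect outright.
* **Suballele labels compare at printed granularity** (`*13C` ≠ `*13`), and
  provisional labels like `4N` are opaque distinct labels.

The packaged GeT-RM 2019 call matrix (21 reference samples × 3 callers)
carries these annotations explicitly; scoring it is the package's primary
reproduction target, and a brute-force occurrence-counting oracle checks the
scorer on 1,000 random diplotypes in the test suite.

# The synthetic cohort generator

No individual-level cohort can be shipped, so all end-to-end behaviour is
exercised on synthetic cohorts with the statistical structure the analysis
assumes:

* Genotypes at each panel site are drawn under Hardy–Weinberg equilibrium,
  `Binomial(2, f)`, independently across variants — no linkage
  disequilibrium, no haplotype blocks, no read-level error model. Passing
  tests therefore demonstrate correctness of the calling/translation
  machinery, not robustness to correlated variation or genotyping error in
  real data.
* The default frequency preset is chosen so the expected number of panel
  variant alleles per genome, Σ2fᵢ, is ≈6, matching what European-ancestry
  WGS cohorts report; it is illustrative, not a population estimate.
* Novel LOF/missense singletons (default 10, mirroring the scale observed
  in a 547-genome cohort) are planted with exactly one heterozygous carrier
  each, with annotations constructed so they classify as intended.
* Explicit scenario plants (e.g. five VKORC1\*2/CYP2C9\*2 double
  homozygotes; one individual carrying CYP2C19 \*17 + \*2 + a novel splice
  variant) override the sampled genotypes. A plant owns its (sample, gene):
  other sampled alleles of that gene are cleared for that sample so the
  scenario is exact. Infeasible plants (homozygote at frequency zero) error.
* Each variant draws from its own RNG sub-stream keyed on (seed, variant
  index), so extending the variant list never perturbs earlier draws and
  fixed seeds give byte-identical VCF output.

Hom-ref rows are emitted at every panel site (gVCF-like), because
distinguishing "\*1" from "no data" is load-bearing for the caller.

Problem sizes used in the shipped test suite — cohorts of 20–547 samples for
generator properties, one 500-genome end-to-end recovery run, 2,000
binomial draws per proportion for CI coverage, 1,000 random diplotypes for
the scorer oracle — were chosen as the smallest sizes at which the
statistical assertions are stable.

# Numerical and degenerate-input choices

* Wilson CC limits are clipped to [0, 1]; x = 0 forces the lower limit to 0
  and x = n the upper to 1.
* `infer_wildtype` with no detected alleles requires an explicit AN; unequal
  AN within a gene is harmonised to the maximum with a warning.
* Multi-allelic records are decomposed before anything else; indels are
  left-aligned to minimal representation with one anchor base.
* Hemizygous/mosaic genotypes are out of scope — all panel genes are
  handled diploid.
* The Medication Safety Card payload is deterministic for identical input
  (a stable content hash identifies the profile); the optional timestamp is
  the only non-reproducible field and is off by default.

# Known limitations

* Phenotype translation is generic across genes; activity-score systems
  (notably CYP2D6) are approximated by the class table, and CYP2D6 tandem
  haplotype function is resolved as the most functional component.
* The recommendation texts are generic summaries keyed by gene and
  phenotype; they are not guideline prose, and only the combined
  VKORC1/CYP2C9 coumarin table carries numeric dose fractions.
* The HCP5 tag is a linkage proxy valid in European-ancestry populations;
  reports carry that caveat verbatim.
* The generator does not simulate LD, population structure (beyond optional
  labels), or genotyping error, so cohort-level results on synthetic data
  validate bookkeeping and statistics, not caller performance on real reads.
* gnomAD-scale sites files are accepted by the same machinery but no
  download or liftover orchestration is provided; one genome build per run.
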