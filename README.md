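# pgxprofiler

Pharmacogenetic (PGx) profiling from whole-genome sequencing variant calls,
for labs that already run diagnostic WGS and want the pharmacogenes it
contains: per-individual star-allele/diplotype calls, metabolizer
phenotypes, DPWG-style drug recommendations and a machine-readable
Medication Safety Card payload — plus the cohort-level view of how much
pharmacogene variation a fixed guideline panel captures, and a scorer for
benchmarking CYP2D6 structural-variant callers against consensus reference
genotypes.

## What it computes

**Panel and profiles.** The bundled panel covers 45 star-allele defining
SNVs/indels in 11 pharmacogenes (*CYP2B6, CYP2C9, CYP2C19, CYP2D6, CYP3A5,
DPYD, F5, SLCO1B1, TPMT, UGT1A1, VKORC1*), the *HCP5* rs2395029 tag for
HLA-B\*57:01, and a slot for externally called CYP2D6 structural alleles
(deletion \*5, duplications ×N, hybrid tandems such as \*68+\*4). From
gVCF-like input (hom-ref records retained, so "\*1" is distinguishable from
"no data") each sample's per-gene diplotype is called under the *trans*
assumption — unphased co-occurring variants are placed on different
haplotypes and flagged — and translated to a phenotype via a declared
DPWG-convention rule table: two no-function alleles → PM, two
increased-function alleles → UM, carrier-style genes (F5, VKORC1, HCP5)
via explicit star-pair rules.

**Landscape.** Cohort- or population-scale inputs (multi-sample or
sites-only VCF) pass a filter cascade (non-PASS, 150-mer mappability < 1),
then a classification cascade (panel match > loss-of-function >
missense damaging by all six of FATHMM, FATHMM-MKL, MutationAssessor,
MutationTaster, PolyPhen-2, SIFT > other; novelty by
ClinVar/HGMD/PharmGKB membership). Per gene, relative allele frequencies
are computed with the wildtype count inferred as AN − Σ AC, with 95%
continuity-corrected Wilson confidence intervals

    low, high = (2np̂ + z² ∓ 1 ∓ z·sqrt(z² ∓ 2 − 1/n + 4p̂(n(1−p̂) ± 1))) / (2(n + z²))

and minor-allele-frequency bins (MAF = min(AC, AN−AC)/AN; <0.1% rare,
0.1–5% low, >5% common).

**CYP2D6 concordance.** Diplotype strings in the full structural grammar
(`*2x2/*71`, `*1/*36x2+*10`, `*3/(*68)+*4`) are parsed and compared
phase-insensitively as allele multisets, honouring caller footnotes
(separately reported hybrids, unassigned duplications, unphased calls) and
per-sample accepted allele equivalences. Scoring the packaged GeT-RM 2019
call matrix (21 samples × Astrolabe/Aldy/Stargazer) reproduces the
published per-caller accuracies.

**Synthetic cohorts.** A deterministic generator draws Hardy–Weinberg
genotypes at the panel sites, plants rare novel LOF/missense singletons and
explicit clinical scenarios, and emits VCF + annotation + truth tables, so
the whole pipeline is testable without any external data.

## Worked example

```r
library(pgxprofiler)
library(tibble)

# score the bundled CYP2D6 caller-comparison matrix
res <- score_cyp2d6_calls(load_cyp2d6_calls())
res
#> CYP2D6 diplotype concordance (21 samples)
#>   aldy       19/21 correct
#>   astrolabe  12/21 correct
#>   stargazer  11/21 correct

# simulate a small cohort with one planted coumarin double homozygote,
# then profile it end to end
spec <- cohort_spec(
  n_samples = 50, seed = 20,
  plants = tibble(sample = 1, gene = c("VKORC1", "CYP2C9"),
                  star_label = "*2", dosage = 2L))
sim  <- generate_cohort(spec, dir = tempdir())
gts  <- read_vcf(sim$paths$vcf, mode = "cohort")
prof <- pgx_profile(gts, annotations = sim$annotations)

dplyr::filter(tidy(prof), sample == "S0001", diplotype != "*1/*1")
#> # A tibble: 5 × 6
#>   sample gene    diplotype alleles   flags                         phenotype
#>   <chr>  <chr>   <chr>     <list>    <chr>                         <chr>
#> 1 S0001  CYP2C9  *2/*2     <chr [2]> ""                            IM
#> 2 S0001  CYP2C19 *1/*17    <chr [2]> ""                            RM
#> 3 S0001  CYP3A5  *1/*3     <chr [2]> "possible_misclassification"  IM
#> 4 S0001  UGT1A1  *1/*28    <chr [2]> ""                            NM
#> 5 S0001  VKORC1  *2/*2     <chr [2]> ""                            high_sensitivity

cat(generate_report(prof, "S0001")$report, sep = "\n")
```

The report lists, per gene, the diplotype, phenotype, caveat flags and the
drugs with guideline actions; for this sample it ends with

```
co-occurring variants:
  CYP3A5: *3,7:99275387:C:A (2 variants in one gene, phase unknown)

coumarin starting dose: 35% of standard (Reduce phenprocoumon/warfarin starting dose to ~35% of standard.)

HLA-B*57:01 tag (abacavir): non_carrier
```

The planted VKORC1 \*2/\*2 + CYP2C9 \*2/\*2 combination triggers the bundled
combined anticoagulant rule — a phenprocoumon/warfarin starting dose of 35%
of standard — and the randomly drawn CYP3A5 gene picked up a novel
loss-of-function variant next to the \*3 allele, so the call is flagged:
unphased, the novel variant could sit on either haplotype and change the
metabolizer interpretation. `write_reports(prof, dir)` writes one
`report.txt` / `profile.json` / `msc.json` triple per sample; the MSC
payload round-trips through `parse_msc()` and is byte-identical for
identical input.

Cohort-level usage follows the same pattern with `mode = "sites"`:
`apply_site_filters()` → `classify_variants()` → `gene_landscape()` /
`summarize_cohort()` / `dpwg_fraction()`, with `plot_landscape()` and
`plot_maf_bins()` for the standard figures, or `run_pipeline()` to drive a
whole stage from files on disk.

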