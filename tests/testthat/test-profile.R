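bundle <- load_bundle()

# tiny two-sample cohort over three panel sites plus full hom-ref backdrop
make_cohort_genotypes <- function(overrides = NULL) {
  panel <- bundle$panel
  si <- panel[panel$variant_kind %in% c("snv", "indel", "tag"), ]
  base <- purrr::map_dfr(c("P1", "P2"), function(smp) {
    tibble::tibble(chrom = si$chrom, pos = si$pos_37, ref = si$ref,
                   alt = si$alt, filter = "PASS", sample = smp,
                   gt = 0L, gt_raw = "0/0", ac = 0L, an = 4L)
  })
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      o <- overrides[i, ]
      row <- si[si$gene == o$gene & si$star_label == o$star_label, ]
      sel <- base$sample == o$sample & base$pos == row$pos_37 &
        base$alt == row$alt
      base$gt[sel] <- o$gt
    }
  }
  base
}

test_that("star calling fills wildtype only for genotyped sites", {
  ov <- tibble::tibble(sample = c("P1", "P1"), gene = c("CYP2C9", "VKORC1"),
                       star_label = c("*2", "*2"), gt = c(1L, 2L))
  gts <- make_cohort_genotypes(ov)
  calls <- call_star_alleles(gts, bundle)
  p1 <- calls[calls$sample == "P1", ]
  expect_equal(p1$diplotype[p1$gene == "CYP2C9"], "*1/*2")
  expect_equal(p1$diplotype[p1$gene == "VKORC1"], "*2/*2")
  expect_equal(p1$diplotype[p1$gene == "TPMT"], "*1/*1")
  # every panel gene appears exactly once per sample
  expect_equal(nrow(p1), dplyr::n_distinct(bundle$panel$gene))
})

test_that("a masked genotype is reported unknown, never imputed to *1", {
  ov <- tibble::tibble(sample = "P1", gene = "CYP2C9", star_label = "*2", gt = 1L)
  gts <- make_cohort_genotypes(ov)
  # drop all TPMT rows for P1 entirely (sites not genotyped)
  tpmt_pos <- bundle$panel$pos_37[bundle$panel$gene == "TPMT"]
  gts <- gts[!(gts$sample == "P1" & gts$pos %in% tpmt_pos), ]
  calls <- call_star_alleles(gts, bundle)
  tp <- calls[calls$sample == "P1" & calls$gene == "TPMT", ]
  expect_equal(tp$diplotype, "?/?")
  expect_match(tp$flags, "allele_unknown")
  # the untouched sample keeps its wildtype call
  expect_equal(calls$diplotype[calls$sample == "P2" & calls$gene == "TPMT"],
               "*1/*1")
})

test_that("more than two alleles keeps the two highest-impact with flags", {
  ov <- tibble::tibble(sample = "P1", gene = "CYP2C19",
                       star_label = c("*2", "*3", "*17"), gt = c(1L, 1L, 1L))
  gts <- make_cohort_genotypes(ov)
  calls <- call_star_alleles(gts, bundle)
  cc <- calls[calls$sample == "P1" & calls$gene == "CYP2C19", ]
  # both kept alleles are the no-function ones
  expect_setequal(cc$alleles[[1]], c("*2", "*3"))
  expect_match(cc$flags, "ambiguous_phase")
  expect_match(cc$flags, "possible_misclassification")
})

test_that("CYP2B6 *9 + *4 at equal dosage combine to *6", {
  ov <- tibble::tibble(sample = "P1", gene = "CYP2B6",
                       star_label = c("*9", "*4"), gt = c(1L, 1L))
  calls <- call_star_alleles(make_cohort_genotypes(ov), bundle)
  expect_equal(calls$diplotype[calls$sample == "P1" & calls$gene == "CYP2B6"],
               "*1/*6")
})

test_that("co-occurrence notes require two relevant variants in one gene", {
  sv <- tibble::tibble(
    sample = c("A", "A", "B"),
    gene = c("CYP2C19", "CYP2C19", "CYP2C9"),
    variant = c("*17", "10:1:C:A", "*2"),
    category = c("dpwg", "lof", "dpwg"),
    novelty = c("n_a", "novel", "n_a")
  )
  notes <- co_occurrence_screen(sv)
  expect_equal(nrow(notes), 1L)
  expect_equal(notes$sample, "A")
  expect_equal(notes$n_variants, 2L)
  expect_true(notes$has_dpwg)
  expect_true(notes$has_novel_lof)
  expect_match(notes$variants, "\\*17")
})

test_that("anticoagulant lookup returns bundled dose fractions", {
  expect_equal(anticoagulant_dose_lookup("*1/*1", "*1/*1", bundle)$dose_fraction, 100)
  expect_equal(anticoagulant_dose_lookup("*2/*2", "*2/*2", bundle)$dose_fraction, 35)
  # combinations without a bundled fraction get action text only
  other <- anticoagulant_dose_lookup("*1/*2", "*2/*2", bundle)
  expect_true(is.na(other$dose_fraction))
  expect_false(other$withheld)
  withheld <- anticoagulant_dose_lookup("*2/*2", "?/?", bundle)
  expect_true(withheld$withheld)
})

test_that("HLA tag status distinguishes unknown from non-carrier", {
  expect_equal(hla_tag_report(1L)$status, "carrier")
  expect_equal(hla_tag_report(0L)$status, "non_carrier")
  expect_equal(hla_tag_report(NA_integer_)$status, "unknown")
  expect_match(hla_tag_report(1L)$caveat, "European")
})

test_that("profiles, reports and card payloads are consistent and deterministic", {
  ov <- tibble::tibble(sample = c("P1", "P1", "P2"),
                       gene = c("CYP2C19", "VKORC1", "HCP5"),
                       star_label = c("*2", "*2", "rs2395029"),
                       gt = c(2L, 2L, 1L))
  gts <- make_cohort_genotypes(ov)
  prof <- pgx_profile(gts, bundle)
  p1 <- tidy(prof)
  expect_equal(p1$phenotype[p1$sample == "P1" & p1$gene == "CYP2C19"], "PM")
  # a PM profile triggers CYP2C19-linked recommendations
  recs <- prof$recommendations
  expect_true("clopidogrel" %in% recs$drug[recs$sample == "P1"])
  # all-wildtype genes carry no recommendations
  expect_false("tacrolimus" %in% recs$drug[recs$sample == "P1"])
  expect_equal(prof$hla$status[prof$hla$sample == "P2"], "carrier")

  rep1 <- generate_report(prof, "P1")
  expect_true(any(grepl("CYP2C19", rep1$report)))
  # payload round-trip reproduces the gene-to-phenotype mapping
  back <- parse_msc(rep1$msc_json)
  expect_equal(unlist(back$genes), unlist(rep1$msc$genes))
  # identical input, byte-identical payload
  prof2 <- pgx_profile(make_cohort_genotypes(ov), bundle)
  rep2 <- generate_report(prof2, "P1")
  expect_identical(rep1$msc_json, rep2$msc_json)

  out <- tempfile()
  write_reports(prof, out)
  expect_true(file.exists(file.path(out, "P1.msc.json")))
  expect_true(file.exists(file.path(out, "P2.report.txt")))

  g <- glance(prof)
  expect_equal(nrow(g), 2L)
  expect_true(all(c("n_genes", "n_recommendations") %in% names(g)))
})

test_that("an all-wildtype profile recommends nothing and adjusts no dose", {
  gts <- make_cohort_genotypes()
  prof <- pgx_profile(gts, bundle)
  expect_equal(nrow(prof$recommendations), 0L)
  expect_true(all(prof$anticoagulant$dose_fraction == 100))
  calls <- tidy(prof)
  expect_true(all(calls$diplotype == "*1/*1"))
  expect_true(all(calls$phenotype[calls$gene == "CYP2C19"] == "NM"))
})
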