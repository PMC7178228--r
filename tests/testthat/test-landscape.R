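test_that("wildtype inference subtracts detected alleles under the trans assumption", {
  expect_equal(infer_wildtype(c(100, 50), an = 1094)$wildtype_ac, 944)
  expect_false(infer_wildtype(c(100, 50), an = 1094)$overflow)
  # co-occurring alleles beyond AN floor at zero with a flag, never an error
  ov <- infer_wildtype(c(800, 400), an = 1000)
  expect_equal(ov$wildtype_ac, 0)
  expect_true(ov$overflow)
  # empty input needs an explicit denominator
  expect_equal(infer_wildtype(integer(0), an = 10)$wildtype_ac, 10)
  expect_error(infer_wildtype(integer(0)))
})

test_that("MAF binning uses the minor allele and fixed boundaries", {
  expect_equal(as.character(maf_bin(1, 1094)), "rare")     # ~0.091%
  expect_equal(as.character(maf_bin(60, 1000)), "common")  # 6%
  expect_equal(as.character(maf_bin(1, 1000)), "low")      # boundary 0.1%
  expect_equal(as.character(maf_bin(50, 1000)), "low")     # boundary 5%
  # high-frequency alternate alleles fold onto the minor allele
  expect_equal(as.character(maf_bin(1090, 1094)), "low")   # minor = 4/1094
  expect_equal(as.character(maf_bin(1094, 1094)), "rare")  # minor = 0
  set.seed(5)
  for (i in 1:200) {
    an <- sample(c(100L, 1094L, 10000L), 1)
    ac <- sample.int(an + 1L, 1) - 1L
    expect_equal(as.character(maf_bin(ac, an)), oracle_maf_bin(ac, an),
                 info = paste(ac, an))
  }
})

test_that("continuity-corrected Wilson interval matches the score-equation roots", {
  expect_equal(wilson_cc_interval(0, 10)$low, 0)
  expect_equal(wilson_cc_interval(10, 10)$high, 1)
  for (n in c(10, 50, 547, 1094)) {
    for (x in unique(c(0, 1, 5, floor(n / 2), n - 1, n))) {
      got <- wilson_cc_interval(x, n)
      want <- oracle_wilson_cc(x, n)
      expect_equal(got$low, unname(want["low"]), tolerance = 1e-6,
                   info = paste(x, n))
      expect_equal(got$high, unname(want["high"]), tolerance = 1e-6,
                   info = paste(x, n))
    }
  }
  expect_error(wilson_cc_interval(5, 0))
  expect_error(wilson_cc_interval(-1, 10))
})

make_classified <- function() {
  tibble::tibble(
    gene = c("CYP3A5", "CYP3A5", "CYP2C9", "CYP2C9", "CYP2C9"),
    chrom = "x", pos = 1:5, ref = "A", alt = "T",
    ac = c(1000L, 4L, 120L, 15L, 1L),
    an = 1094L,
    category = c("dpwg", "lof", "dpwg", "dpwg", "lof"),
    novelty = c("n_a", "novel", "n_a", "n_a", "novel"),
    star_label = c("*3", NA, "*2", "*3", NA)
  )
}

test_that("gene landscape conserves alleles and exposes the wildtype row", {
  land <- gene_landscape(make_classified())
  by_gene <- split(land, land$gene)
  for (g in names(by_gene)) {
    expect_equal(sum(by_gene[[g]]$ac), by_gene[[g]]$an[1], info = g)
    expect_equal(sum(by_gene[[g]]$frequency), 1, tolerance = 1e-9, info = g)
  }
  # CYP3A5*3-style majority allele: wildtype is not the most frequent
  c3 <- by_gene$CYP3A5
  wt <- c3[c3$category == "wildtype", ]
  expect_lt(wt$frequency, max(c3$frequency))
  expect_equal(wt$ac, 1094 - 1004)
  g <- glance(land)
  expect_equal(nrow(g), 2L)
  expect_false(any(g$overflow))
})

test_that("cohort summary tallies categories by MAF bin with totals", {
  s <- summarize_cohort(make_classified())
  tot <- s[s$maf_bin == "total", ]
  expect_equal(tot$n_variants[tot$group == "dpwg"], 3L)
  expect_equal(tot$n_alleles[tot$group == "dpwg"], 1135L)
  expect_equal(tot$n_variants[tot$group == "novel_lof_missense"], 2L)
  rare_novel <- s[s$group == "novel_lof_missense" & s$maf_bin == "rare", ]
  expect_equal(rare_novel$n_variants, 1L)
  # empty input gives an all-zero table of the same shape
  empty <- summarize_cohort(make_classified()[0, ])
  expect_true(all(empty$n_variants == 0L))
  expect_equal(nrow(empty), 12L)
})

test_that("DPWG allele share is computed per gene and overall", {
  cls <- make_classified()
  fr <- dpwg_fraction(cls)
  expect_equal(fr$overall, 100 * (1000 + 120 + 15) / sum(cls$ac))
  expect_equal(fr$per_gene$pct_dpwg[fr$per_gene$gene == "CYP3A5"],
               100 * 1000 / 1004)
  all_dpwg <- dplyr::mutate(cls, category = "dpwg")
  expect_equal(dpwg_fraction(all_dpwg)$overall, 100)
  no_dpwg <- dplyr::mutate(cls, category = "lof", novelty = "novel")
  expect_equal(dpwg_fraction(no_dpwg)$overall, 0)
  expect_error(dpwg_fraction(cls[0, ]), "no detected")
})

test_that("reduced/no-function CYP2D6 share is computed from the count table", {
  s <- cyp2d6_function_share()
  expect_equal(s$share_pct, 100 * (93 + 25 + 123 + 71 + 30) / 1094)
  expect_equal(s$share_rounded_pct, 30)
})

test_that("landscape plots build without error", {
  land <- gene_landscape(make_classified())
  p <- plot_landscape(land)
  expect_s3_class(p, "ggplot")
  p2 <- plot_maf_bins(summarize_cohort(make_classified()))
  expect_s3_class(p2, "ggplot")
})
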