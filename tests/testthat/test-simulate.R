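bundle <- load_bundle()

test_that("zero frequencies and no plants give an all-wildtype cohort", {
  freqs <- default_frequencies()
  freqs$freq <- 0
  spec <- cohort_spec(n_samples = 5, seed = 1, frequencies = freqs,
                      n_novel = 0, n_known_lof = 0)
  sim <- generate_cohort(spec, bundle)
  expect_true(all(sim$genotypes$gt == 0L))
  calls <- call_star_alleles(sim$genotypes, bundle)
  expect_true(all(calls$diplotype == "*1/*1"))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- cohort_spec(n_samples = 20, seed = 42)
  d1 <- tempfile()
  d2 <- tempfile()
  generate_cohort(spec, bundle, dir = d1)
  generate_cohort(spec, bundle, dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))
  # and a different seed changes the draw
  d3 <- tempfile()
  generate_cohort(cohort_spec(n_samples = 20, seed = 43), bundle, dir = d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("extending the variant list does not perturb earlier draws", {
  spec_a <- cohort_spec(n_samples = 50, seed = 9, n_novel = 0, n_known_lof = 0)
  spec_b <- cohort_spec(n_samples = 50, seed = 9, n_novel = 6, n_known_lof = 2)
  ga <- generate_cohort(spec_a, bundle)$genotypes
  gb <- generate_cohort(spec_b, bundle)$genotypes
  shared <- dplyr::semi_join(gb, ga, by = c("chrom", "pos", "ref", "alt"))
  expect_equal(dplyr::arrange(shared, chrom, pos, alt, sample)$gt,
               dplyr::arrange(ga, chrom, pos, alt, sample)$gt)
})

test_that("sampled heterozygosity tracks 2f(1-f)", {
  spec <- cohort_spec(n_samples = 2000, seed = 77, n_novel = 0, n_known_lof = 0)
  sim <- generate_cohort(spec, bundle)
  truth <- sim$truth
  gts <- sim$genotypes
  for (k in which(truth$freq >= 0.05 & truth$freq <= 0.95)) {
    key <- truth$key[k]
    g <- gts$gt[paste(gts$chrom, gts$pos, gts$ref, gts$alt, sep = ":") == key]
    f <- truth$freq[k]
    p_het <- 2 * f * (1 - f)
    se <- sqrt(p_het * (1 - p_het) / length(g))
    expect_lt(abs(mean(g == 1L) - p_het), 4 * se,
              label = paste("heterozygosity at", key))
  }
})

test_that("plants override sampled genotypes and are bookkept", {
  plants <- tibble::tibble(
    sample = c(1:5, 6, 6, 6),
    gene = c(rep("VKORC1", 5), "CYP2C19", "CYP2C19", "CYP2C19"),
    star_label = c(rep("*2", 5), "*17", "*2", "novel:splice_acceptor_variant"),
    dosage = c(rep(2L, 5), 1L, 1L, 1L)
  )
  plants2 <- dplyr::bind_rows(plants, tibble::tibble(
    sample = 1:5, gene = "CYP2C9", star_label = "*2", dosage = 2L
  ))
  spec <- cohort_spec(n_samples = 30, seed = 3, plants = plants2)
  sim <- generate_cohort(spec, bundle)
  # exactly 5 double homozygotes in the truth table
  dh <- sim$plant_truth |>
    dplyr::filter(dosage == 2L) |>
    dplyr::group_by(sample) |>
    dplyr::summarise(both = all(c("VKORC1", "CYP2C9") %in% gene), .groups = "drop")
  expect_equal(sum(dh$both), 5L)
  # planted genotypes present in the emitted genotypes
  v2 <- bundle$panel[bundle$panel$gene == "VKORC1", ]
  g <- sim$genotypes
  expect_true(all(g$gt[g$pos == v2$pos_37 & g$sample %in% sprintf("S%04d", 1:5)] == 2L))
  # infeasible plant: homozygote at a frequency-zero variant
  f0 <- default_frequencies()
  f0$freq <- 0
  bad <- cohort_spec(n_samples = 5, seed = 2, frequencies = f0,
                     plants = tibble::tibble(sample = 1, gene = "VKORC1",
                                             star_label = "*2", dosage = 2L))
  expect_error(generate_cohort(bad, bundle), "infeasible")
})

test_that("sites generator injects decoys that the filter cascade removes", {
  spec <- cohort_spec(n_samples = 547, seed = 8, n_novel = 0, n_known_lof = 0)
  s0 <- generate_sites(spec, bundle)
  expect_true(all(s0$sites$filter == "PASS"))
  expect_true(all(s0$sites$mappability == 1))
  s <- generate_sites(spec, bundle, decoy_nonpass = 3, decoy_lowmap = 2)
  filt <- apply_site_filters(s$sites)
  expect_equal(sum(!filt$retained), 5L)
  expect_setequal(unique(filt$filter_reason[!filt$retained]),
                  c("non_pass", "low_mappability"))
  expect_true(all(filt$retained[!filt$is_decoy]))
})

test_that("sites allele counts follow binomial moments", {
  freqs <- default_frequencies()
  freqs$freq <- 0.01
  an <- 2L * 547L
  acs <- unlist(lapply(1:25, function(s) {
    spec <- cohort_spec(n_samples = 547, seed = 1000 + s, frequencies = freqs,
                        n_novel = 0, n_known_lof = 0)
    generate_sites(spec, bundle)$sites$ac
  }))
  mu <- an * 0.01
  se <- sqrt(an * 0.01 * 0.99) / sqrt(length(acs))
  expect_lt(abs(mean(acs) - mu), 3 * se)
})

test_that("the default frequency preset implies about six variant alleles per genome", {
  f <- default_frequencies()
  expect_true(abs(sum(2 * f$freq) - 6) < 0.5)
})
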