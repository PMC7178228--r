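bundle <- load_bundle()
panel <- bundle$panel

test_that("bundled panel has the expected shape", {
  si <- panel[panel$variant_kind %in% c("snv", "indel"), ]
  expect_equal(nrow(si), 45L)
  expect_equal(dplyr::n_distinct(si$gene), 11L)
  expect_setequal(unique(si$gene),
                  c("CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A5", "DPYD",
                    "F5", "SLCO1B1", "TPMT", "UGT1A1", "VKORC1"))
  expect_false(any(duplicated(panel[, c("gene", "star_label")])))
  expect_true(all(si$ref != si$alt))
  # tag variant present at its GRCh37 position
  tag <- panel[panel$variant_kind == "tag", ]
  expect_equal(tag$gene, "HCP5")
  expect_equal(tag$pos_37, 31431780L)
  expect_equal(tag$ref, "T")
  expect_equal(tag$alt, "G")
  # structural-variant slots for CYP2D6 deletion and duplication
  expect_setequal(panel$star_label[panel$variant_kind == "sv_slot"], c("*5", "xN"))
})

test_that("loading reports counts and rejects bad panels", {
  expect_message(load_panel(), "45 SNV/indel")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(character(0), tmp)
  expect_error(load_panel(tmp, quiet = TRUE))
  # duplicate (gene, star_label)
  dup <- dplyr::bind_rows(panel, panel[1, ])
  write_panel(dup, tmp)
  expect_error(load_panel(tmp, quiet = TRUE), "duplicate")
  # dropping a variant is a warning, not an error (user-extensible panel)
  write_panel(panel[-1, ], tmp)
  expect_warning(load_panel(tmp, quiet = TRUE), "44 SNV/indel")
})

test_that("panel round-trips through write/load", {
  tmp <- tempfile(fileext = ".tsv")
  write_panel(panel, tmp)
  back <- load_panel(tmp, quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(panel))
  expect_equal(attr(back, "bundle_version"), attr(panel, "bundle_version"))
})

test_that("coordinate lookup is exact-match on either build", {
  hit <- lookup_variant(panel, "7", 99270539, "T", "C", build = "GRCh37")
  expect_equal(hit$gene, "CYP3A5")
  expect_equal(hit$star_label, "*3")
  expect_equal(hit$hgvs_c, "c.219-237A>G")
  # a non-panel site returns no rows
  expect_equal(nrow(lookup_variant(panel, "7", 12345, "A", "G", "GRCh37")), 0L)
  # every entry resolves to itself on both stored coordinate sets
  si <- panel[panel$variant_kind %in% c("snv", "indel", "tag"), ]
  for (i in seq_len(nrow(si))) {
    h37 <- lookup_variant(panel, si$chrom[i], si$pos_37[i], si$ref[i], si$alt[i],
                          "GRCh37")
    h38 <- lookup_variant(panel, si$chrom[i], si$pos_38[i], si$ref[i], si$alt[i],
                          "GRCh38")
    expect_true(si$star_label[i] %in% h37$star_label, info = si$star_label[i])
    expect_true(si$star_label[i] %in% h38$star_label, info = si$star_label[i])
    expect_setequal(paste(h37$gene, h37$star_label), paste(h38$gene, h38$star_label))
  }
  # representation-dependent indel input still matches (left-alignment)
  u28 <- panel[panel$gene == "UGT1A1" & panel$star_label == "*28", ]
  hit <- lookup_variant(panel, u28$chrom, u28$pos_37, "AT", "ATAT", "GRCh37")
  expect_equal(hit$star_label, "*28")
  expect_error(lookup_variant(panel, "7", 1, "A", "G", build = "hg18"))
})

test_that("phenotype translation matches DPWG anchors and is total", {
  expect_equal(translate_phenotype("CYP2C19", "*1/*1", bundle)$phenotype, "NM")
  expect_equal(translate_phenotype("CYP2C19", "*2/*2", bundle)$phenotype, "PM")
  expect_equal(translate_phenotype("CYP2C19", "*17/*17", bundle)$phenotype, "UM")
  expect_equal(translate_phenotype("CYP2C19", "*2/*17", bundle)$phenotype, "IM")
  expect_equal(translate_phenotype("VKORC1", "*2/*2", bundle)$phenotype,
               "high_sensitivity")
  expect_equal(translate_phenotype("F5", "*1/Leiden", bundle)$phenotype, "carrier")
  expect_error(translate_phenotype("NOTAGENE", "*1/*1", bundle), "not covered")
  # unknown allele function propagates
  res <- translate_phenotype("CYP2D6", "*1/*999", bundle)
  expect_equal(res$phenotype, "unknown")
  expect_equal(res$flag, "unknown_allele_function")
  # totality over the four function classes
  classes <- c("no_function", "decreased", "normal", "increased")
  rules <- bundle$phenotype_rules[bundle$phenotype_rules$kind == "class", ]
  keys <- vapply(seq_len(nrow(rules)), function(i) {
    paste(sort(c(rules$allele1[i], rules$allele2[i])), collapse = "|")
  }, "")
  for (a in classes) for (b in classes) {
    expect_true(paste(sort(c(a, b)), collapse = "|") %in% keys,
                info = paste(a, b))
  }
})

test_that("CYP2D6 haplotype strings resolve to function classes", {
  expect_equal(allele_function("CYP2D6", "*4", bundle), "no_function")
  expect_equal(allele_function("CYP2D6", "*68+*4", bundle), "no_function")
  expect_equal(allele_function("CYP2D6", "*36+*10", bundle), "decreased")
  expect_equal(allele_function("CYP2D6", "*2x2", bundle), "increased")
  expect_equal(allele_function("CYP2D6", "*5", bundle), "no_function")
})

test_that("recommendation bundle covers 77 drugs plus the contraceptive group", {
  recs <- bundle$recommendations
  expect_equal(dplyr::n_distinct(recs$drug[recs$is_group == "no"]), 77L)
  expect_true("oral contraceptives" %in% recs$drug[recs$is_group == "yes"])
  expect_false(any(duplicated(recs[, c("gene", "phenotypes", "drug")])))
  # every recommendation gene resolves against the panel
  expect_true(all(recs$gene %in% panel$gene))
})
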