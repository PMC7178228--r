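#' Call star alleles and diplotypes from cohort genotypes
#'
#' Every alternate allele observed at a panel site contributes its star
#' allele to the sample's per-gene allele multiset; the remaining
#' haplotype(s) are filled with *1 only when all panel sites of that gene
#' were genotyped — a missing genotype yields an explicit unknown allele
#' (`?`) with flag `allele_unknown`, never a silent wildtype. Variants in
#' the same gene are assumed in trans, so two heterozygous variants form a
#' two-allele diplotype carrying flag `ambiguous_phase`. When more than two
#' alleles are assigned, the two highest-impact alleles (no function >
#' decreased > increased > normal) are kept and the call is additionally
#' flagged `possible_misclassification`. Star-combination definitions
#' (e.g. CYP2B6 *9 + *4 at equal dosage = *6) are applied first.
#'
#' @param genotypes Cohort genotype tibble from
#'   [read_vcf()]`(mode = "cohort")`.
#' @param bundle A `pgx_bundle`.
#' @param build Genome build of the input coordinates.
#' @return Tibble with one row per sample and panel gene: `sample`, `gene`,
#'   `diplotype`, `alleles` (list column), `flags` (`;`-separated or `""`).
#' @export
call_star_alleles <- function(genotypes, bundle, build = "GRCh37") {
  stopifnot(inherits(bundle, "pgx_bundle"), is.data.frame(genotypes))
  panel <- bundle$panel
  sites <- panel[panel$variant_kind %in% c("snv", "indel", "tag"), ]
  pos_col <- if (build == "GRCh37") "pos_37" else "pos_38"
  key_panel <- .variant_key(.norm_chrom(sites$chrom), sites[[pos_col]],
                            sites$ref, sites$alt)
  gt <- genotypes |>
    dplyr::mutate(.key = .variant_key(.norm_chrom(.data$chrom), .data$pos,
                                      .data$ref, .data$alt))
  samples <- unique(genotypes$sample)
  genes <- unique(sites$gene)
  impact_rank <- c(no_function = 1, decreased = 2, increased = 3,
                   normal = 4, unknown = 5)

  out <- purrr::map_dfr(samples, function(smp) {
    g_s <- gt[gt$sample == smp, ]
    purrr::map_dfr(genes, function(gene) {
      gs <- sites[sites$gene == gene, ]
      keys <- key_panel[sites$gene == gene]
      dos <- vapply(seq_len(nrow(gs)), function(j) {
        m <- g_s$gt[g_s$.key == keys[j]]
        if (!length(m)) NA_integer_ else m[1]
      }, 1L)
      missing_sites <- is.na(dos)
      dos[missing_sites] <- 0L
      labs <- gs$star_label
      # star combinations: components at equal non-zero dosage merge
      comb <- bundle$combinations[bundle$combinations$gene == gene, ]
      if (nrow(comb)) {
        for (ci in seq_len(nrow(comb))) {
          parts <- strsplit(comb$components[ci], "+", fixed = TRUE)[[1]]
          idx <- match(parts, labs)
          if (!anyNA(idx) && !any(missing_sites[idx])) {
            d <- dos[idx]
            if (length(unique(d)) == 1L && d[1] > 0L) {
              dos[idx] <- 0L
              labs <- c(labs, comb$result[ci])
              dos <- c(dos, d[1])
              missing_sites <- c(missing_sites, FALSE)
            }
          }
        }
      }
      alleles <- rep(labs, dos)
      flags <- character(0)
      n_het_sites <- sum(dos == 1L)
      if (length(alleles) > 2L) {
        fns <- vapply(alleles, function(l) allele_function(gene, l, bundle), "")
        keep <- order(impact_rank[fns])[1:2]
        alleles <- alleles[keep]
        flags <- c(flags, "ambiguous_phase", "possible_misclassification")
      } else if (n_het_sites >= 2L && length(alleles) == 2L) {
        flags <- c(flags, "ambiguous_phase")
      }
      if (any(missing_sites) && length(alleles) < 2L) {
        alleles <- c(alleles, rep("?", 2L - length(alleles)))
        flags <- c(flags, "allele_unknown")
      } else {
        alleles <- c(alleles, rep("*1", max(0L, 2L - length(alleles))))
      }
      alleles <- ifelse(startsWith(alleles, "*") | alleles == "?",
                        alleles, paste0("*", alleles))
      alleles <- alleles[order(alleles == "?", alleles)]
      tibble::tibble(sample = smp, gene = gene,
                     diplotype = paste(alleles, collapse = "/"),
                     alleles = list(alleles),
                     flags = paste(unique(flags), collapse = ";"))
    })
  })
  out
}

#' Screen for co-occurring variants in the same gene
#'
#' Flags samples carrying two or more pharmacogenetically relevant variants
#' (DPWG and/or LOF/consensus-damaging missense) in one gene — unphased,
#' these may sit in cis and change the metabolizer interpretation (e.g. a
#' novel splice LOF next to an increased-function promoter allele).
#'
#' @param sample_variants Tibble with one row per sample and carried
#'   variant: columns `sample`, `gene`, `variant` (identity: star label or
#'   coordinate key), `category` (`dpwg`/`lof`/`damaging_missense`).
#' @return Tibble of notes: `sample`, `gene`, `n_variants`, `variants`
#'   (comma-joined identities), `has_dpwg`, `has_novel_lof`.
#' @export
co_occurrence_screen <- function(sample_variants) {
  stopifnot(is.data.frame(sample_variants))
  if (!"novelty" %in% names(sample_variants)) sample_variants$novelty <- "novel"
  rel <- dplyr::filter(sample_variants,
                       .data$category %in% c("dpwg", "lof", "damaging_missense"))
  if (!nrow(rel)) {
    return(tibble::tibble(sample = character(0), gene = character(0),
                          n_variants = integer(0), variants = character(0),
                          has_dpwg = logical(0), has_novel_lof = logical(0)))
  }
  rel |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(
      n_variants = dplyr::n_distinct(.data$variant),
      variants = paste(sort(unique(.data$variant)), collapse = ","),
      has_dpwg = any(.data$category == "dpwg"),
      has_novel_lof = any(.data$category != "dpwg" & .data$novelty == "novel"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_variants >= 2L)
}

#' Combined VKORC1/CYP2C9 coumarin starting-dose lookup
#'
#' Looks up the bundled phenprocoumon/warfarin starting-dose table for a
#' pair of resolved diplotypes. Combinations without a bundled dose
#' fraction return action text only; if either diplotype contains an
#' unknown allele, guidance is withheld.
#'
#' @param vkorc1,cyp2c9 Diplotype strings (e.g. `"*2/*2"`).
#' @param bundle A `pgx_bundle`.
#' @return List with `dose_fraction` (percent of standard starting dose or
#'   `NA`), `action`, and `withheld` (logical).
#'
#' @examples
#' anticoagulant_dose_lookup("*2/*2", "*2/*2")$dose_fraction  # 35
#' @export
anticoagulant_dose_lookup <- function(vkorc1, cyp2c9, bundle = load_bundle()) {
  norm <- function(d) {
    a <- sort(strsplit(d, "/", fixed = TRUE)[[1]])
    paste(a, collapse = "/")
  }
  if (grepl("\\?", vkorc1) || grepl("\\?", cyp2c9)) {
    return(list(dose_fraction = NA_real_,
                action = "Dose guidance withheld: unresolved diplotype.",
                withheld = TRUE))
  }
  tab <- bundle$anticoagulant
  hit <- vapply(seq_len(nrow(tab)), function(i) {
    norm(tab$vkorc1[i]) == norm(vkorc1) && norm(tab$cyp2c9[i]) == norm(cyp2c9)
  }, TRUE)
  if (any(hit)) {
    i <- which(hit)[1]
    list(dose_fraction = as.numeric(tab$dose_fraction[i]),
         action = tab$action_text[i], withheld = FALSE)
  } else {
    list(dose_fraction = NA_real_,
         action = "No bundled dose fraction for this combination; individualized coumarin dosing advised.",
         withheld = FALSE)
  }
}

#' Abacavir risk note from the HLA-B*57:01 tag variant
#'
#' The HCP5 variant rs2395029 is used as a linkage marker for HLA-B*57:01
#' in populations of European ancestry; carriers must not receive abacavir
#' without confirmatory HLA typing. A missing genotype yields status
#' `unknown`, never `non_carrier`.
#'
#' @param dosage Alternate-allele dosage at the tag site (0, 1, 2, or `NA`
#'   when the site was not genotyped).
#' @return List with `status` (`carrier`/`non_carrier`/`unknown`) and
#'   `caveat` text.
#' @export
hla_tag_report <- function(dosage) {
  caveat <- paste("rs2395029 (HCP5) tags HLA-B*57:01 in European-ancestry",
                  "populations only; confirm by sequence-based HLA typing",
                  "before acting in other ancestries.")
  if (is.na(dosage)) return(list(status = "unknown", caveat = caveat))
  list(status = if (dosage > 0) "carrier" else "non_carrier", caveat = caveat)
}

#' Build per-sample PGx profiles for a cohort
#'
#' End-to-end per-individual profiling: star-allele/diplotype calls (with
#' external CYP2D6 SV diplotypes merged in when supplied), metabolizer
#' phenotypes, drug recommendations, co-occurrence caveats, the combined
#' VKORC1/CYP2C9 anticoagulant lookup, and the HLA-B*57:01 tag report.
#'
#' @param genotypes Cohort genotype tibble (from
#'   [read_vcf()]`(mode = "cohort")`).
#' @param bundle A `pgx_bundle`.
#' @param annotations Optional annotation tibble; when given, non-panel
#'   variants are classified and screened for co-occurrence with panel
#'   variants.
#' @param sv_table Optional CYP2D6 SV diplotype tibble
#'   (see [merge_sv_calls()]).
#' @param build Genome build.
#' @return Object of class `pgx_profile`: list with tibbles `calls`
#'   (sample x gene: diplotype, phenotype, flags), `recommendations`,
#'   `co_occurrence`, `anticoagulant`, `hla`, plus `version`. `tidy()`
#'   returns `calls`; `glance()` one row per sample with summary counts.
#' @export
pgx_profile <- function(genotypes, bundle = load_bundle(), annotations = NULL,
                        sv_table = NULL, build = "GRCh37") {
  calls <- call_star_alleles(genotypes, bundle, build = build)
  calls <- merge_sv_calls(calls, sv_table)
  ph <- purrr::map2(calls$gene, calls$diplotype, function(g, d) {
    if (grepl("\\?", d)) return(list(phenotype = "unknown", flag = "allele_unknown"))
    translate_phenotype(g, d, bundle)
  })
  calls$phenotype <- vapply(ph, function(x) x$phenotype, "")
  extra <- vapply(ph, function(x) x$flag %||% NA_character_, "")
  calls$flags <- purrr::map2_chr(calls$flags, extra, function(f, e) {
    if (is.na(e) || !nzchar(e) || grepl(e, f, fixed = TRUE)) return(f)
    if (nzchar(f)) paste(f, e, sep = ";") else e
  })

  # co-occurrence screen over panel + classified non-panel variants
  co <- tibble::tibble(sample = character(0), gene = character(0),
                       n_variants = integer(0), variants = character(0),
                       has_dpwg = logical(0), has_novel_lof = logical(0))
  if (!is.null(annotations)) {
    sites <- genotypes |>
      dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                      .data$filter, .data$ac, .data$an)
    ann_gene <- if ("gene" %in% names(annotations)) {
      dplyr::select(annotations, "chrom", "pos", "ref", "alt", "gene")
    } else NULL
    if (!is.null(ann_gene)) {
      sites <- dplyr::left_join(sites, ann_gene, by = c("chrom", "pos", "ref", "alt"))
    } else {
      sites$gene <- NA_character_
    }
    cls <- classify_variants(sites, annotations, bundle$panel, build = build)
    cls <- cls |>
      dplyr::mutate(variant = ifelse(!is.na(.data$star_label), .data$star_label,
                                     .variant_key(.data$chrom, .data$pos,
                                                  .data$ref, .data$alt)))
    carried <- genotypes |>
      dplyr::filter(!is.na(.data$gt), .data$gt > 0) |>
      dplyr::inner_join(
        dplyr::select(cls, "chrom", "pos", "ref", "alt", "gene", "variant",
                      "category", "novelty"),
        by = c("chrom", "pos", "ref", "alt")
      ) |>
      dplyr::select("sample", "gene", "variant", "category", "novelty")
    co <- co_occurrence_screen(carried)
    # an unphased novel LOF/missense next to panel variants can overturn the
    # diplotype interpretation: flag the affected gene call
    risky <- co[co$has_novel_lof & co$has_dpwg, c("sample", "gene")]
    if (nrow(risky)) {
      idx <- match(paste(risky$sample, risky$gene),
                   paste(calls$sample, calls$gene))
      idx <- idx[!is.na(idx)]
      calls$flags[idx] <- ifelse(
        grepl("possible_misclassification", calls$flags[idx], fixed = TRUE),
        calls$flags[idx],
        ifelse(nzchar(calls$flags[idx]),
               paste(calls$flags[idx], "possible_misclassification", sep = ";"),
               "possible_misclassification")
      )
    }
  }

  # recommendations: actionable phenotype x bundled drug table; fire only
  # when a variant allele was actually detected (all-wildtype diplotypes,
  # even when their phenotype is nominally actionable as for the CYP3A5
  # expresser state, yield no deviation from standard care)
  recs <- calls |>
    dplyr::filter(.data$diplotype != "*1/*1") |>
    dplyr::select("sample", "gene", "phenotype") |>
    dplyr::inner_join(bundle$recommendations, by = "gene",
                      relationship = "many-to-many")
  actionable <- purrr::map2_lgl(recs$phenotype, recs$phenotypes, function(p, ps) {
    p %in% strsplit(ps, "|", fixed = TRUE)[[1]]
  })
  recs <- recs[actionable, c("sample", "gene", "phenotype", "drug", "action_text")]

  # anticoagulant screen
  wide <- calls |>
    dplyr::filter(.data$gene %in% c("VKORC1", "CYP2C9")) |>
    dplyr::select("sample", "gene", "diplotype") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "diplotype")
  anticoag <- purrr::pmap_dfr(wide, function(sample, VKORC1, CYP2C9) {
    r <- anticoagulant_dose_lookup(VKORC1, CYP2C9, bundle)
    tibble::tibble(sample = sample, vkorc1 = VKORC1, cyp2c9 = CYP2C9,
                   dose_fraction = r$dose_fraction, action = r$action,
                   withheld = r$withheld)
  })

  # HLA tag
  tag <- bundle$panel[bundle$panel$variant_kind == "tag", ]
  pos_col <- if (build == "GRCh37") "pos_37" else "pos_38"
  tag_key <- .variant_key(.norm_chrom(tag$chrom), tag[[pos_col]], tag$ref, tag$alt)
  hla <- purrr::map_dfr(unique(genotypes$sample), function(smp) {
    g <- genotypes[genotypes$sample == smp &
                     .variant_key(.norm_chrom(genotypes$chrom), genotypes$pos,
                                  genotypes$ref, genotypes$alt) == tag_key, ]
    r <- hla_tag_report(if (nrow(g)) g$gt[1] else NA_integer_)
    tibble::tibble(sample = smp, status = r$status, caveat = r$caveat)
  })

  structure(list(calls = calls, recommendations = recs, co_occurrence = co,
                 anticoagulant = anticoag, hla = hla,
                 version = bundle$version),
            class = "pgx_profile")
}

#' @export
print.pgx_profile <- function(x, ...) {
  cat("PGx profile:", dplyr::n_distinct(x$calls$sample), "sample(s),",
      dplyr::n_distinct(x$calls$gene), "genes; bundle", x$version, "\n")
  invisible(x)
}

#' @export
#' @rdname pgx_profile
#' @method tidy pgx_profile
#' @param x A `pgx_profile`.
#' @param ... Unused.
tidy.pgx_profile <- function(x, ...) x$calls

#' @export
#' @rdname pgx_profile
#' @method glance pgx_profile
glance.pgx_profile <- function(x, ...) {
  x$calls |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_non_wildtype = sum(.data$diplotype != "*1/*1"),
      n_flagged = sum(nzchar(.data$flags)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::count(x$recommendations, .data$sample, name = "n_recommendations"),
      by = "sample"
    ) |>
    dplyr::mutate(n_recommendations = tidyr::replace_na(.data$n_recommendations, 0L))
}

# stable 32-bit polynomial hash of a character payload; profile identifier
# for the machine-readable card (not cryptographic)
.payload_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Render a PGx report and Medication Safety Card payload for one sample
#'
#' The report is a plain-text per-gene listing (diplotype, phenotype,
#' caveat flags, drug recommendations); the card payload is a compact JSON
#' object (sample, guideline version, gene-to-phenotype codes, stable
#' profile identifier suitable for QR encoding). The payload is
#' deterministic for identical input apart from the `generated` timestamp,
#' which can be suppressed.
#'
#' @param profile A `pgx_profile`.
#' @param sample Sample identifier (default: first sample in the profile).
#' @param timestamp Include a generation timestamp in the payload.
#' @return List with `report` (character vector of lines), `msc` (payload
#'   list), and `msc_json` (serialized payload).
#' @export
generate_report <- function(profile, sample = NULL, timestamp = FALSE) {
  stopifnot(inherits(profile, "pgx_profile"))
  sample <- sample %||% profile$calls$sample[1]
  calls <- dplyr::filter(profile$calls, .data$sample == !!sample) |>
    dplyr::arrange(.data$gene)
  if (!nrow(calls)) stop("sample not in profile: ", sample)
  recs <- dplyr::filter(profile$recommendations, .data$sample == !!sample)
  co <- dplyr::filter(profile$co_occurrence, .data$sample == !!sample)
  ac <- dplyr::filter(profile$anticoagulant, .data$sample == !!sample)
  hla <- dplyr::filter(profile$hla, .data$sample == !!sample)

  lines <- c(
    paste0("PGx report - sample ", sample),
    paste0("guideline bundle: ", profile$version),
    ""
  )
  for (i in seq_len(nrow(calls))) {
    g <- calls$gene[i]
    lines <- c(lines, sprintf("%-8s %-14s %-18s %s", g, calls$diplotype[i],
                              calls$phenotype[i],
                              ifelse(nzchar(calls$flags[i]), paste0("[", calls$flags[i], "]"), "")))
    rg <- recs[recs$gene == g, ]
    if (nrow(rg)) {
      lines <- c(lines, paste0("  drugs: ", paste(sort(rg$drug), collapse = ", ")))
    }
  }
  if (nrow(co)) {
    lines <- c(lines, "", "co-occurring variants:")
    lines <- c(lines, sprintf("  %s: %s (%d variants in one gene, phase unknown)",
                              co$gene, co$variants, co$n_variants))
  }
  if (nrow(ac) && !is.na(ac$dose_fraction[1])) {
    lines <- c(lines, "", sprintf("coumarin starting dose: %g%% of standard (%s)",
                                  ac$dose_fraction[1], ac$action[1]))
  }
  if (nrow(hla)) {
    lines <- c(lines, "", paste0("HLA-B*57:01 tag (abacavir): ", hla$status[1]))
  }

  genes <- setNames(as.list(calls$phenotype), calls$gene)
  core <- jsonlite::toJSON(list(sample = sample, bundle = profile$version,
                                genes = genes),
                           auto_unbox = TRUE)
  msc <- list(
    schema = "msc/1",
    sample = sample,
    bundle = profile$version,
    genes = genes,
    profile_id = .payload_hash(as.character(core))
  )
  if (timestamp) msc$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  list(report = lines, msc = msc,
       msc_json = as.character(jsonlite::toJSON(msc, auto_unbox = TRUE, pretty = TRUE)))
}

#' Parse a Medication Safety Card payload
#'
#' Round-trips the JSON payload written by [generate_report()] back into
#' the gene-to-phenotype mapping.
#'
#' @param json MSC payload string.
#' @return The payload as a list; `genes` is a named list.
#' @export
parse_msc <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = FALSE)
}

#' Write report, profile and card files for every sample
#'
#' @param profile A `pgx_profile`.
#' @param out_dir Output directory; one `<sample>.report.txt`,
#'   `<sample>.profile.json`, `<sample>.msc.json` triple per sample.
#' @return Tibble of written paths, invisibly.
#' @export
write_reports <- function(profile, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  purrr::map_dfr(unique(profile$calls$sample), function(smp) {
    r <- generate_report(profile, smp)
    rp <- file.path(out_dir, paste0(smp, ".report.txt"))
    pp <- file.path(out_dir, paste0(smp, ".profile.json"))
    mp <- file.path(out_dir, paste0(smp, ".msc.json"))
    writeLines(r$report, rp)
    jsonlite::write_json(
      dplyr::filter(profile$calls, .data$sample == smp) |>
        dplyr::select(-"alleles"),
      pp, auto_unbox = TRUE, pretty = TRUE
    )
    writeLines(r$msc_json, mp)
    tibble::tibble(sample = smp, report = rp, profile = pp, msc = mp)
  }) |> invisible()
}
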