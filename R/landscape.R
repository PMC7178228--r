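#' Infer the wildtype (*1) allele count for a gene
#'
#' Short-read data leave panel variants unphased, so multiple variants
#' detected in one gene are assumed to lie in trans (on different
#' haplotypes). The wildtype count is then the total allele number minus
#' the sum of detected variant alleles. When detected alleles exceed the
#' total (co-occurring variants violating the trans assumption) the count
#' floors at zero and the result is flagged — the assumption is known to
#' underestimate wildtype alleles, never to error out.
#'
#' @param acs Integer vector of per-variant alternate allele counts for one
#'   gene.
#' @param an Total allele number (2 x samples for a diploid cohort);
#'   required explicitly when `acs` is empty.
#' @return List with `wildtype_ac` and `overflow` (logical).
#'
#' @examples
#' infer_wildtype(c(100, 50), an = 1094)  # 944 wildtype alleles
#' @export
infer_wildtype <- function(acs, an) {
  stopifnot(length(an) == 1L, !is.na(an), an >= 0)
  wt <- an - sum(acs)
  list(wildtype_ac = max(wt, 0), overflow = wt < 0)
}

#' Minor-allele-frequency bin
#'
#' MAF is `min(ac, an - ac) / an` (the minor allele — high-frequency
#' variants such as CYP3A5*3 exceed 50% alternate-allele frequency). Bins:
#' rare `[0, 0.1%)`, low `[0.1%, 5%]`, common `(5%, 50%]`; the bins
#' partition the MAF range, with both printed boundaries assigned to the
#' low-frequency bin.
#'
#' @param ac,an Alternate allele count and total allele number (vectorised).
#' @return Factor with levels `rare`, `low`, `common`.
#' @export
maf_bin <- function(ac, an) {
  stopifnot(all(an > 0), all(ac >= 0), all(ac <= an))
  maf <- pmin(ac, an - ac) / an
  cut(maf, breaks = c(-Inf, 0.001, 0.05, Inf), right = FALSE,
      labels = c("rare", "low", "common")) |>
    (\(b) {
      # cut() with right=FALSE puts 5% in 'common'; the bundled convention
      # keeps both boundaries in the low bin
      b[maf == 0.05] <- "low"
      b
    })()
}

#' Continuity-corrected Wilson score interval
#'
#' 95% (by default) confidence interval for a binomial proportion using the
#' Wilson score method with correction for continuity (Newcombe method 4;
#' the interval produced by classic proportion calculators). Conservative:
#' empirical coverage is at least nominal for the proportions arising in
#' allele-frequency work.
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param conf Confidence level, default 0.95.
#' @return Tibble with columns `low`, `high`, clipped to `[0, 1]`; `low` is
#'   0 when `x = 0` and `high` is 1 when `x = n`.
#' @export
wilson_cc_interval <- function(x, n, conf = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n), conf > 0, conf < 1)
  k <- max(length(x), length(n))
  x <- rep_len(x, k)
  n <- rep_len(n, k)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  low <- (2 * n * p + z^2 - 1 -
            z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / (2 * (n + z^2))
  high <- (2 * n * p + z^2 + 1 +
             z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / (2 * (n + z^2))
  low[x == 0] <- 0
  high[x == n] <- 1
  tibble::tibble(low = pmin(pmax(low, 0), 1), high = pmin(pmax(high, 0), 1))
}

#' Per-gene allele-frequency landscape
#'
#' For each gene, relative frequencies of every detected variant allele
#' (DPWG star alleles by label, LOF/missense variants by coordinate key)
#' plus the inferred wildtype row, with continuity-corrected 95% CIs.
#' Frequencies per gene sum to 1; wildtype + detected alleles conserve the
#' total allele number (asserted on every build).
#'
#' @param classified Classified site tibble (from [classify_variants()])
#'   with `gene`, `ac`, `an`, `category`, `novelty` columns; rows with
#'   category `other` are ignored.
#' @param an Total allele number; default the maximum `an` seen per gene
#'   (harmonised with a warning if sites disagree).
#' @param conf Confidence level for the CIs.
#' @return A tibble of class `gene_landscape`: one row per allele per gene
#'   (`allele = "*1 (wildtype)"` for the inferred wildtype) with `ac`,
#'   `an`, `frequency`, `ci_low`, `ci_high`, `category`, `novelty`,
#'   `overflow`.
#' @export
gene_landscape <- function(classified, an = NULL, conf = 0.95) {
  stopifnot(is.data.frame(classified))
  rel <- dplyr::filter(classified, .data$category %in% c("dpwg", "lof", "damaging_missense"),
                       .data$ac > 0)
  out <- rel |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      an_g <- an %||% max(df$an)
      if (length(unique(df$an)) > 1L) {
        warning("unequal AN within gene ", key$gene, "; harmonising to maximum",
                call. = FALSE)
      }
      wt <- infer_wildtype(df$ac, an_g)
      allele <- ifelse(!is.na(df$star_label), df$star_label,
                       .variant_key(df$chrom, df$pos, df$ref, df$alt))
      rows <- tibble::tibble(
        allele = c(allele, "*1 (wildtype)"),
        ac = c(df$ac, wt$wildtype_ac),
        an = an_g,
        category = c(df$category, "wildtype"),
        novelty = c(df$novelty, "n_a"),
        overflow = wt$overflow
      )
      ci <- wilson_cc_interval(rows$ac, rows$an, conf = conf)
      rows$frequency <- rows$ac / rows$an
      rows$ci_low <- ci$low
      rows$ci_high <- ci$high
      rows
    }) |>
    dplyr::ungroup()
  # conservation: wildtype + detected variant alleles = AN within each gene
  check <- out |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ok = sum(.data$ac) == .data$an[1] | any(.data$overflow),
                     .groups = "drop")
  stopifnot(all(check$ok))
  structure(out, class = c("gene_landscape", class(out)))
}

#' Cohort summary by variant category and MAF bin
#'
#' Counts of variants and alleles for each classification category (DPWG,
#' known LOF/missense, novel LOF/missense) broken down by MAF bin, with
#' within-category percentages and a totals row per category — the shape of
#' a pharmacogene-landscape summary table.
#'
#' @param classified Classified site tibble with `ac`, `an`, `category`,
#'   `novelty`; only detected variants (`ac > 0`) are tallied.
#' @return A tibble with columns `group`, `maf_bin` (`"total"` row
#'   included), `n_variants`, `n_alleles`, `pct_variants`.
#' @export
summarize_cohort <- function(classified) {
  stopifnot(is.data.frame(classified))
  det <- dplyr::filter(classified, .data$ac > 0,
                       .data$category %in% c("dpwg", "lof", "damaging_missense"))
  if (!nrow(det)) {
    return(tidyr::expand_grid(
      group = c("novel_lof_missense", "known_lof_missense", "dpwg"),
      maf_bin = c("total", "common", "low", "rare")
    ) |>
      dplyr::mutate(n_variants = 0L, n_alleles = 0L, pct_variants = 0))
  }
  det <- det |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$category == "dpwg" ~ "dpwg",
        .data$novelty == "novel" ~ "novel_lof_missense",
        TRUE ~ "known_lof_missense"
      ),
      maf_bin = as.character(maf_bin(.data$ac, .data$an))
    )
  bins <- det |>
    dplyr::group_by(.data$group, .data$maf_bin) |>
    dplyr::summarise(n_variants = dplyr::n(), n_alleles = sum(.data$ac),
                     .groups = "drop")
  all_bins <- tidyr::expand_grid(
    group = c("novel_lof_missense", "known_lof_missense", "dpwg"),
    maf_bin = c("common", "low", "rare")
  )
  bins <- dplyr::left_join(all_bins, bins, by = c("group", "maf_bin")) |>
    dplyr::mutate(dplyr::across(c("n_variants", "n_alleles"),
                                ~ tidyr::replace_na(.x, 0L)))
  totals <- bins |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(maf_bin = "total", n_variants = sum(.data$n_variants),
                     n_alleles = sum(.data$n_alleles), .groups = "drop")
  dplyr::bind_rows(totals, bins) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct_variants = 100 * .data$n_variants /
                    max(.data$n_variants[.data$maf_bin == "total"][1], 1L)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$group, c("novel_lof_missense", "known_lof_missense", "dpwg")),
                   match(.data$maf_bin, c("total", "common", "low", "rare")))
}

#' Share of detected alleles on the DPWG panel
#'
#' Of all detected pharmacogene alleles (DPWG + LOF + consensus-damaging
#' missense), the percentage contributed by DPWG panel variants — overall
#' and per gene.
#'
#' @param classified Classified site tibble.
#' @return List with `overall` (percentage scalar) and `per_gene` (tibble).
#' @export
dpwg_fraction <- function(classified) {
  det <- dplyr::filter(classified, .data$ac > 0,
                       .data$category %in% c("dpwg", "lof", "damaging_missense"))
  if (!nrow(det)) stop("no detected alleles to summarise")
  per_gene <- det |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      dpwg_alleles = sum(.data$ac[.data$category == "dpwg"]),
      total_alleles = sum(.data$ac),
      pct_dpwg = 100 * .data$dpwg_alleles / .data$total_alleles,
      .groups = "drop"
    )
  list(
    overall = 100 * sum(det$ac[det$category == "dpwg"]) / sum(det$ac),
    per_gene = per_gene
  )
}

#' Reduced/no-function share of CYP2D6 star alleles
#'
#' From a table of per-allele counts with function classes, the percentage
#' of alleles whose star allele has decreased or no function. The packaged
#' default table carries the most frequent CYP2D6 alleles reported for a
#' 547-genome WGS cohort (1094 alleles).
#'
#' @param counts Tibble with columns `allele`, `count`, `function_class`;
#'   default: the packaged in-house CYP2D6 count table.
#' @param total_alleles Denominator; default 2 x 547.
#' @return List with `share_pct` (exact percentage) and `share_rounded_pct`
#'   (rounded to the nearest ten percent).
#' @export
cyp2d6_function_share <- function(counts = NULL, total_alleles = 1094L) {
  counts <- counts %||% readr::read_tsv(
    system.file("extdata", "cohort", "cyp2d6_inhouse_allele_counts.tsv",
                package = "pgxprofiler", mustWork = TRUE),
    comment = "#", show_col_types = FALSE
  )
  stopifnot(all(c("allele", "count", "function_class") %in% names(counts)))
  reduced <- sum(counts$count[counts$function_class %in% c("decreased", "no_function")])
  pct <- 100 * reduced / total_alleles
  list(share_pct = pct, share_rounded_pct = round(pct / 10) * 10)
}
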