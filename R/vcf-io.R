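#' Read a VCF into a tidy site/genotype table
#'
#' Reads VCF 4.x (plain or bgzipped) via \pkg{vcfR}, decomposes multi-allelic
#' records into biallelic rows, left-aligns indels, and retains gVCF-like
#' homozygous-reference rows — required downstream to distinguish a *1 call
#' from a no-call at a panel site.
#'
#' @param path VCF file.
#' @param mode `"sites"` for sites-only input (allele counts taken from the
#'   `AC`/`AN` INFO fields, per-population `AC_*`/`AN_*` fields carried
#'   along), `"cohort"` for multi-sample input with genotypes.
#' @param build Declared genome build (`"GRCh37"` or `"GRCh38"`); stored in
#'   the `"build"` attribute and checked against the `##reference` header
#'   line when one is present.
#'
#' @return A tibble. In `sites` mode one row per biallelic site with columns
#'   `chrom`, `pos`, `ref`, `alt`, `filter`, `ac`, `an` (plus any
#'   per-population count columns). In `cohort` mode one row per site and
#'   sample with `sample`, `gt` (alt-allele dosage 0/1/2, `NA` for no-call)
#'   and `gt_raw`, plus cohort `ac`/`an` computed over called genotypes.
#' @export
read_vcf <- function(path, mode = c("sites", "cohort"), build = "GRCh37") {
  mode <- match.arg(mode)
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  ref_line <- grep("^##reference", meta, value = TRUE)
  if (length(ref_line)) {
    stated <- if (grepl("38", ref_line[1])) "GRCh38" else if (grepl("37|hg19", ref_line[1])) "GRCh37" else NA
    if (!is.na(stated) && stated != build) {
      stop("declared build ", build, " does not match VCF header: ", ref_line[1])
    }
  }
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))
  fix$pos <- as.integer(fix$pos)
  gt_mat <- if (ncol(v@gt) > 1L) v@gt else NULL
  if (mode == "cohort" && is.null(gt_mat)) stop("cohort mode requires genotype columns")

  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) >= 2L) x[2] else NA_character_, "")
  }
  pop_keys <- unique(unlist(regmatches(
    fix$info, gregexpr("(?:^|;)(A[CN]_[A-Za-z]+)=", fix$info)
  )))
  pop_keys <- unique(sub("^;?", "", sub("=$", "", pop_keys)))

  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$alt[i], ",", fixed = TRUE)[[1]]
    ref <- fix$ref[i]
    is_homref_row <- length(alts) == 1L && alts[1] %in% c(".", "<NON_REF>", "")
    if (is_homref_row) alts <- NA_character_
    acs <- strsplit(info_field(fix$info[i], "AC"), ",", fixed = TRUE)[[1]]
    an <- suppressWarnings(as.integer(info_field(fix$info[i], "AN")))
    purrr::map_dfr(seq_along(alts), function(k) {
      if (is.na(alts[k])) {
        base <- tibble::tibble(chrom = fix$chrom[i], pos = fix$pos[i],
                               ref = ref, alt = NA_character_,
                               filter = fix$filter[i],
                               ac = 0L, an = an %||% NA_integer_,
                               .row = i, .alt_idx = 0L)
      } else {
        nn <- normalize_allele(fix$pos[i], ref, alts[k])
        base <- tibble::tibble(chrom = fix$chrom[i], pos = nn$pos,
                               ref = nn$ref, alt = nn$alt,
                               filter = fix$filter[i],
                               ac = suppressWarnings(as.integer(acs[k])),
                               an = an, .row = i, .alt_idx = k)
      }
      for (pk in pop_keys) {
        vals <- strsplit(info_field(fix$info[i], pk), ",", fixed = TRUE)[[1]]
        base[[tolower(pk)]] <- suppressWarnings(
          as.integer(if (startsWith(pk, "AC")) vals[max(base$.alt_idx, 1L)] else vals[1])
        )
      }
      base
    })
  })

  if (mode == "sites") {
    out <- dplyr::select(rows, -".row", -".alt_idx")
  } else {
    samples <- colnames(gt_mat)[-1]
    gt_fields <- strsplit(gt_mat[, "FORMAT"], ":", fixed = TRUE)
    gt_idx <- vapply(gt_fields, function(f) match("GT", f), 1L)
    if (anyNA(gt_idx)) stop("cohort mode requires a GT FORMAT field on every record")
    out <- purrr::map_dfr(seq_len(nrow(rows)), function(j) {
      i <- rows$.row[j]
      k <- rows$.alt_idx[j]
      raw <- vapply(seq_along(samples), function(s) {
        parts <- strsplit(gt_mat[i, s + 1L], ":", fixed = TRUE)[[1]]
        parts[gt_idx[i]]
      }, "")
      alleles <- strsplit(raw, "[/|]")
      dosage <- vapply(alleles, function(a) {
        if (any(a %in% c(".", ""))) return(NA_integer_)
        if (k == 0L) 0L else sum(a == as.character(k))
      }, 1L)
      tibble::tibble(
        chrom = rows$chrom[j], pos = rows$pos[j], ref = rows$ref[j],
        alt = rows$alt[j], filter = rows$filter[j],
        sample = samples, gt = dosage, gt_raw = raw
      )
    })
    counts <- out |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::summarise(ac = sum(.data$gt, na.rm = TRUE),
                       an = 2L * sum(!is.na(.data$gt)), .groups = "drop")
    out <- dplyr::left_join(out, counts, by = c("chrom", "pos", "ref", "alt"))
  }
  attr(out, "build") <- build
  out
}

#' Read the per-variant annotation table
#'
#' The annotation TSV is keyed by `chrom`, `pos`, `ref`, `alt` and carries
#' the consequence term, the six missense-predictor verdicts (`fathmm`,
#' `fathmm_mkl`, `mutation_assessor`, `mutation_taster`, `polyphen2`,
#' `sift`), database-membership flags (`clinvar_drug_response`,
#' `hgmd_class`, `pharmgkb`), 150-mer `mappability`, and optionally a
#' `splice_pred` verdict for near-splice-site variants.
#'
#' @param path Annotation TSV.
#' @return A tibble with `pos` as integer and all other columns character.
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           pos = readr::col_integer(),
                           mappability = readr::col_double(),
                           .default = readr::col_character()
                         ))
  need <- c("chrom", "pos", "ref", "alt", "consequence")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) stop("annotation table missing columns: ",
                            paste(missing, collapse = ", "))
  tbl
}

#' Apply the site-level filter cascade
#'
#' High-confidence filtering: sites with a non-PASS filter status and sites
#' with 150-mer mappability below the threshold are excluded. Every input
#' row is returned, annotated with `retained` and a machine-readable
#' `filter_reason` (`"non_pass"`, `"low_mappability"`, or `NA` for retained
#' rows), so retained and excluded records always partition the input.
#'
#' @param records Site tibble (from [read_vcf()]), optionally already
#'   carrying a `mappability` column.
#' @param annotations Optional annotation tibble supplying `mappability`
#'   (joined on `chrom`, `pos`, `ref`, `alt`).
#' @param min_mappability Minimum mappability retained (default 1.0, i.e.
#'   uniquely mappable only).
#' @param require_pass Exclude records whose `FILTER` is not `PASS`/`.`.
#' @return The input tibble plus `mappability`, `retained`, `filter_reason`.
#' @export
apply_site_filters <- function(records, annotations = NULL,
                               min_mappability = 1.0, require_pass = TRUE) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(dplyr::mutate(records, retained = logical(0), filter_reason = character(0)))
  }
  if (!"mappability" %in% names(records)) {
    if (!is.null(annotations) && "mappability" %in% names(annotations)) {
      records <- dplyr::left_join(
        records,
        dplyr::select(annotations, "chrom", "pos", "ref", "alt", "mappability"),
        by = c("chrom", "pos", "ref", "alt")
      )
    } else {
      records$mappability <- NA_real_
    }
  }
  if (anyNA(records$mappability)) {
    warning("mappability missing for ", sum(is.na(records$mappability)),
            " records; treating as 1.0", call. = FALSE)
    records$mappability[is.na(records$mappability)] <- 1.0
  }
  stopifnot(all(records$mappability >= 0 & records$mappability <= 1))
  non_pass <- require_pass & !records$filter %in% c("PASS", ".", NA)
  low_map <- records$mappability < min_mappability
  records$retained <- !(non_pass | low_map)
  records$filter_reason <- dplyr::case_when(
    non_pass ~ "non_pass",
    low_map ~ "low_mappability",
    TRUE ~ NA_character_
  )
  records
}

#' Keep only records retained by the filter cascade
#'
#' @param records Output of [apply_site_filters()].
#' @return The retained rows.
#' @export
filter_retained <- function(records) {
  stopifnot("retained" %in% names(records))
  dplyr::filter(records, .data$retained)
}

#' Attach external CYP2D6 structural-variant diplotypes
#'
#' CYP2D6 deletions, duplications and hybrid tandems are not callable from
#' the panel SNVs/indels alone; an external SV caller supplies per-sample
#' diplotype strings which replace the SNV-derived CYP2D6 diplotype.
#' Samples missing from the SV table keep their SNV-derived diplotype and
#' are flagged `sv_unknown`; a whole-gene double deletion (`*5/*5`) that
#' contradicts observed CYP2D6 SNV alleles is flagged `sv_conflict`.
#'
#' @param diplotypes Per-sample/gene diplotype tibble (from
#'   [call_star_alleles()]), with columns `sample`, `gene`, `diplotype`,
#'   `flags`.
#' @param sv_table Tibble with columns `sample` and `cyp2d6` (diplotype
#'   strings in the grammar of [parse_diplotype()]), or `NULL`.
#' @return `diplotypes` with CYP2D6 rows updated.
#' @export
merge_sv_calls <- function(diplotypes, sv_table = NULL) {
  stopifnot(is.data.frame(diplotypes))
  is_d6 <- diplotypes$gene == "CYP2D6"
  if (!any(is_d6)) return(diplotypes)
  add_flag <- function(flags, new) ifelse(is.na(flags) | !nzchar(flags),
                                          new, paste(flags, new, sep = ";"))
  if (is.null(sv_table)) {
    diplotypes$flags[is_d6] <- add_flag(diplotypes$flags[is_d6], "sv_unknown")
    return(diplotypes)
  }
  stopifnot(all(c("sample", "cyp2d6") %in% names(sv_table)))
  for (i in which(is_d6)) {
    smp <- diplotypes$sample[i]
    sv <- sv_table$cyp2d6[sv_table$sample == smp]
    if (!length(sv) || is.na(sv[1]) || !nzchar(sv[1])) {
      diplotypes$flags[i] <- add_flag(diplotypes$flags[i], "sv_unknown")
      next
    }
    parsed <- parse_diplotype(sv[1]) # errors on malformed strings
    old <- diplotypes$diplotype[i]
    diplotypes$diplotype[i] <- render_diplotype(parsed)
    diplotypes$flags[i] <- add_flag(diplotypes$flags[i], "sv_integrated")
    old_alleles <- setdiff(allele_multiset(parse_diplotype(old)), "1")
    if (identical(sort(allele_multiset(parsed)), c("5", "5")) && length(old_alleles)) {
      diplotypes$flags[i] <- add_flag(diplotypes$flags[i], "sv_conflict")
    }
  }
  diplotypes
}
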