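#' Illustrative European-ancestry allele frequencies for the bundled panel
#'
#' A frequency preset for the synthetic-cohort generator chosen so that the
#' expected number of panel variant alleles per genome (sum of 2f over
#' variants) is approximately six, matching what WGS cohorts of primarily
#' European ancestry observe. Values are illustrative defaults for
#' simulation, not population estimates.
#'
#' @param panel A `pgx_panel`.
#' @return Tibble `gene`, `star_label`, `freq` covering every SNV/indel and
#'   tag entry of the panel (unlisted variants get frequency 0.0005).
#' @export
default_frequencies <- function(panel = load_panel(quiet = TRUE)) {
  preset <- c(
    "CYP3A5|*3" = 0.93, "VKORC1|*2" = 0.40, "UGT1A1|*28" = 0.30,
    "CYP2B6|*9" = 0.24, "CYP2C19|*17" = 0.22, "CYP2D6|*4" = 0.18,
    "CYP2C19|*2" = 0.15, "SLCO1B1|*5" = 0.15, "CYP2C9|*2" = 0.12,
    "CYP2D6|*41" = 0.09, "CYP2C9|*3" = 0.07, "CYP2B6|*4" = 0.05,
    "CYP2B6|*5" = 0.06, "TPMT|*3C" = 0.04, "TPMT|*3B" = 0.03,
    "CYP2D6|*9" = 0.025, "CYP2D6|*10" = 0.02, "CYP2D6|*3" = 0.01,
    "CYP2D6|*6" = 0.01, "F5|Leiden" = 0.02, "HCP5|rs2395029" = 0.035,
    "UGT1A1|*6" = 0.01, "DPYD|c.1236G>A" = 0.012, "DPYD|*2A" = 0.005,
    "CYP2B6|*18" = 0.0, "CYP2C9|*5" = 0.0, "CYP3A5|*6" = 0.0
  )
  si <- panel[panel$variant_kind %in% c("snv", "indel", "tag"), ]
  key <- paste(si$gene, si$star_label, sep = "|")
  tibble::tibble(
    gene = si$gene, star_label = si$star_label,
    freq = ifelse(key %in% names(preset), unname(preset[key]), 0.0005)
  )
}

#' Specify a synthetic diploid cohort
#'
#' The generator emulates a jointly-called WGS cohort genotyped at the
#' panel sites: genotypes are drawn per variant under Hardy-Weinberg
#' equilibrium at the given allele frequency, independently across variants
#' (no linkage disequilibrium); rare novel LOF/missense singletons are
#' added below a frequency ceiling; explicit per-sample scenarios
#' ("plants") override the sampled genotypes and are recorded in the truth
#' table.
#'
#' @param n_samples Cohort size (default 547).
#' @param seed Mandatory integer seed; each variant draws from its own
#'   sub-stream so extending the variant list does not perturb earlier
#'   draws.
#' @param frequencies Tibble `gene`, `star_label`, `freq`
#'   (default [default_frequencies()]).
#' @param n_novel Number of novel LOF/missense singleton variants
#'   (default 10, one carrier each, i.e. MAF well below 0.1% at cohort
#'   scale).
#' @param novel_consequences Consequence mix cycled over the novel
#'   variants.
#' @param n_known_lof Number of database-listed (known) LOF/missense
#'   variants simulated at low frequency.
#' @param known_lof_freqs Frequencies for those known variants.
#' @param plants Tibble of planted genotypes with columns `sample`
#'   (1-based index), `gene`, `star_label`, `dosage` (1 or 2); use
#'   `star_label = "novel:<consequence>"` to plant a private novel variant.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 547L, seed, frequencies = NULL,
                        n_novel = 10L,
                        novel_consequences = c("stop_gained",
                                               "frameshift_variant",
                                               "splice_acceptor_variant",
                                               "missense_variant"),
                        n_known_lof = 4L,
                        known_lof_freqs = c(0.01, 0.0025, 0.0015, 0.001),
                        plants = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  frequencies <- frequencies %||% default_frequencies()
  stopifnot(all(frequencies$freq >= 0 & frequencies$freq <= 1),
            n_samples >= 1L, n_novel >= 0L, n_known_lof >= 0L)
  if (!is.null(plants)) {
    stopifnot(all(c("sample", "gene", "star_label", "dosage") %in% names(plants)),
              all(plants$dosage %in% 1:2),
              all(plants$sample >= 1 & plants$sample <= n_samples))
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 frequencies = frequencies, n_novel = as.integer(n_novel),
                 novel_consequences = novel_consequences,
                 n_known_lof = as.integer(n_known_lof),
                 known_lof_freqs = rep_len(known_lof_freqs, n_known_lof),
                 plants = plants),
            class = "cohort_spec")
}

# panel genes cycled over for placing simulated non-panel variants; offsets
# keep synthetic sites clear of real panel coordinates
.novel_site <- function(panel, k) {
  si <- panel[panel$variant_kind %in% c("snv", "indel"), ]
  genes <- sort(unique(si$gene))
  g <- genes[(k - 1L) %% length(genes) + 1L]
  row <- si[si$gene == g, ][1, ]
  list(gene = g, chrom = row$chrom,
       pos_37 = row$pos_37 + 1000L + 37L * k,
       pos_38 = row$pos_38 + 1000L + 37L * k)
}

#' Generate a synthetic cohort: genotypes, annotations, truth
#'
#' Draws HWE genotypes at every panel site (emitting homozygous-reference
#' rows too, gVCF-like), adds known and novel LOF/missense variants,
#' applies plants, and builds the matching annotation table so that every
#' simulated variant classifies as intended. With `dir` set, writes
#' `cohort.vcf`, `annotations.tsv` and `truth.tsv`.
#'
#' @param spec A `cohort_spec`.
#' @param bundle A `pgx_bundle`.
#' @param dir Optional output directory.
#' @param build Build used for emitted coordinates.
#' @return List with `genotypes` (long tibble as from
#'   [read_vcf()]`(mode="cohort")`), `annotations`, `truth` (per-variant:
#'   key, gene, label, true class/novelty, frequency used, allele count),
#'   `plant_truth` (per planted genotype), `samples`, and file `paths`
#'   when written.
#' @export
generate_cohort <- function(spec, bundle = load_bundle(), dir = NULL,
                            build = "GRCh37") {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- bundle$panel
  pos_col <- if (build == "GRCh37") "pos_37" else "pos_38"
  si <- panel[panel$variant_kind %in% c("snv", "indel", "tag"), ]
  n <- spec$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  freqs <- dplyr::left_join(
    si[, c("gene", "star_label", "chrom", pos_col, "ref", "alt")],
    spec$frequencies, by = c("gene", "star_label")
  )
  freqs$freq[is.na(freqs$freq)] <- 0
  names(freqs)[names(freqs) == pos_col] <- "pos"

  # panel genotypes: HWE via Binomial(2, f), one RNG sub-stream per variant
  gmat <- matrix(0L, nrow = nrow(freqs), ncol = n)
  for (i in seq_len(nrow(freqs))) {
    set.seed(.derive_seed(spec$seed, i))
    gmat[i, ] <- rbinom(n, 2L, freqs$freq[i])
  }

  variants <- freqs |>
    dplyr::mutate(label = .data$star_label, category = "dpwg", novelty = "n_a",
                  consequence = "intron_variant", source = "panel")

  # known (database-listed) LOF variants at low frequency
  extra <- list()
  k_off <- nrow(freqs)
  if (spec$n_known_lof > 0L) {
    for (k in seq_len(spec$n_known_lof)) {
      site <- .novel_site(panel, k)
      f <- spec$known_lof_freqs[k]
      set.seed(.derive_seed(spec$seed, k_off + k))
      g <- rbinom(n, 2L, f)
      extra[[length(extra) + 1L]] <- list(
        row = tibble::tibble(gene = site$gene, star_label = NA_character_,
                             chrom = site$chrom, pos = site[[pos_col]],
                             ref = "G", alt = "T", freq = f,
                             label = paste0("known_lof_", k),
                             category = "lof", novelty = "known",
                             consequence = "stop_gained", source = "known_lof"),
        g = g
      )
    }
  }
  # novel singleton LOF/missense variants: exactly one heterozygous carrier
  if (spec$n_novel > 0L) {
    for (k in seq_len(spec$n_novel)) {
      site <- .novel_site(panel, 100L + k)
      cons <- spec$novel_consequences[(k - 1L) %% length(spec$novel_consequences) + 1L]
      set.seed(.derive_seed(spec$seed, k_off + 1000L + k))
      carrier <- sample.int(n, 1L)
      g <- integer(n)
      g[carrier] <- 1L
      extra[[length(extra) + 1L]] <- list(
        row = tibble::tibble(gene = site$gene, star_label = NA_character_,
                             chrom = site$chrom, pos = site[[pos_col]],
                             ref = "C", alt = "A", freq = 1 / (2 * n),
                             label = paste0("novel_", k),
                             category = if (cons == "missense_variant")
                               "damaging_missense" else "lof",
                             novelty = "novel",
                             consequence = cons, source = "novel"),
        g = g
      )
    }
  }

  # plants override sampled genotypes; planted novels add private variants
  plant_truth <- tibble::tibble(sample = character(0), gene = character(0),
                                label = character(0), dosage = integer(0))
  if (!is.null(spec$plants)) {
    # a plant owns its (sample, gene): sampled genotypes at the gene's other
    # panel sites are cleared so the scenario is exactly as specified
    own <- unique(spec$plants[, c("sample", "gene")])
    for (q in seq_len(nrow(own))) {
      gi <- which(variants$gene == own$gene[q])
      gmat[gi, own$sample[q]] <- 0L
    }
    for (p in seq_len(nrow(spec$plants))) {
      pl <- spec$plants[p, ]
      smp_i <- pl$sample
      if (startsWith(pl$star_label, "novel:")) {
        cons <- sub("^novel:", "", pl$star_label)
        gene_rows <- panel[panel$gene == pl$gene & panel$variant_kind != "sv_slot", ]
        g <- integer(n)
        g[smp_i] <- pl$dosage
        lab <- paste0("planted_novel_", p)
        extra[[length(extra) + 1L]] <- list(
          row = tibble::tibble(gene = pl$gene, star_label = NA_character_,
                               chrom = gene_rows$chrom[1],
                               pos = gene_rows[[pos_col]][1] + 2000L + 37L * p,
                               ref = "T", alt = "G", freq = pl$dosage / (2 * n),
                               label = lab,
                               category = if (cons == "missense_variant")
                                 "damaging_missense" else "lof",
                               novelty = "novel", consequence = cons,
                               source = "planted_novel"),
          g = g
        )
      } else {
        i <- which(variants$gene == pl$gene & variants$star_label == pl$star_label)
        if (!length(i)) stop("plant refers to unknown panel variant: ",
                             pl$gene, " ", pl$star_label)
        if (freqs$freq[i[1]] == 0 && pl$dosage == 2L) {
          stop("infeasible plant: homozygote planted at frequency-0 variant ",
               pl$gene, " ", pl$star_label)
        }
        gmat[i[1], smp_i] <- pl$dosage
        lab <- pl$star_label
      }
      plant_truth <- dplyr::bind_rows(plant_truth, tibble::tibble(
        sample = samples[smp_i], gene = pl$gene, label = lab, dosage = pl$dosage
      ))
    }
  }

  if (length(extra)) {
    variants <- dplyr::bind_rows(variants, purrr::map_dfr(extra, "row"))
    gmat <- rbind(gmat, do.call(rbind, purrr::map(extra, "g")))
  }
  variants$ac <- as.integer(rowSums(gmat))
  variants$an <- 2L * n

  # long genotype tibble mirroring read_vcf(mode = "cohort") output
  genotypes <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    tibble::tibble(chrom = variants$chrom[i], pos = variants$pos[i],
                   ref = variants$ref[i], alt = variants$alt[i],
                   filter = "PASS", sample = samples,
                   gt = gmat[i, ],
                   gt_raw = c("0/0", "0/1", "1/1")[gmat[i, ] + 1L],
                   ac = variants$ac[i], an = variants$an[i])
  })

  annotations <- variants |>
    dplyr::mutate(
      fathmm = ifelse(.data$category == "damaging_missense", "D", "T"),
      fathmm_mkl = .data$fathmm, mutation_assessor = .data$fathmm,
      mutation_taster = .data$fathmm, polyphen2 = .data$fathmm,
      sift = .data$fathmm,
      splice_pred = ifelse(grepl("splice", .data$consequence), "altering",
                           NA_character_),
      clinvar_drug_response = ifelse(.data$novelty == "known", "drug_response", ""),
      hgmd_class = ifelse(.data$novelty == "known", "DM", ""),
      pharmgkb = ifelse(.data$novelty == "known", "yes", ""),
      mappability = 1
    ) |>
    dplyr::select("chrom", "pos", "ref", "alt", "gene", "consequence",
                  dplyr::all_of(.predictor_cols), "splice_pred",
                  "clinvar_drug_response", "hgmd_class", "pharmgkb",
                  "mappability")

  truth <- variants |>
    dplyr::mutate(key = .variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    dplyr::select("key", "gene", "label", "category", "novelty",
                  "freq", "ac", "an", "source")

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(dir, "cohort.vcf")
    .write_cohort_vcf(variants, gmat, samples, vcf_path, build)
    ann_path <- file.path(dir, "annotations.tsv")
    readr::write_tsv(annotations, ann_path)
    truth_path <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, truth_path)
    paths <- list(vcf = vcf_path, annotations = ann_path, truth = truth_path)
  }

  list(genotypes = genotypes, annotations = annotations, truth = truth,
       plant_truth = plant_truth, samples = samples, paths = paths)
}

# VCF 4.2 multi-sample emission for simulated records (gVCF-like: rows with
# all-reference genotypes are written, not dropped)
.write_cohort_vcf <- function(variants, gmat, samples, path, build) {
  ord <- order(variants$chrom, variants$pos, variants$alt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", build),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(ord, function(i) {
    gts <- c("0/0", "0/1", "1/1")[gmat[i, ] + 1L]
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS",
            paste0("AC=", variants$ac[i], ";AN=", variants$an[i]),
            "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a sites-only VCF with allele counts
#'
#' Emulates a population-database (gnomAD-style) sites file over the panel:
#' per variant, AC is drawn Binomial(AN, f). Filter-cascade decoys
#' (non-PASS rows and low-mappability rows) are injected at configurable
#' rates to exercise [apply_site_filters()].
#'
#' @param spec A `cohort_spec` (frequencies and seed reused; `AN = 2 *
#'   n_samples`).
#' @param bundle A `pgx_bundle`.
#' @param decoy_nonpass,decoy_lowmap Number of decoy records of each kind
#'   (default 0).
#' @param dir Optional output directory (writes `sites.vcf` and
#'   `site_annotations.tsv`).
#' @param build Coordinate build.
#' @return List with `sites` tibble (including `mappability` and truth
#'   columns `freq`, `is_decoy`), `annotations`, and `paths`.
#' @export
generate_sites <- function(spec, bundle = load_bundle(), decoy_nonpass = 0L,
                           decoy_lowmap = 0L, dir = NULL, build = "GRCh37") {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- bundle$panel
  pos_col <- if (build == "GRCh37") "pos_37" else "pos_38"
  si <- panel[panel$variant_kind %in% c("snv", "indel", "tag"), ]
  an <- 2L * spec$n_samples
  freqs <- dplyr::left_join(
    si[, c("gene", "star_label", "chrom", pos_col, "ref", "alt")],
    spec$frequencies, by = c("gene", "star_label")
  )
  freqs$freq[is.na(freqs$freq)] <- 0
  names(freqs)[names(freqs) == pos_col] <- "pos"
  acs <- integer(nrow(freqs))
  for (i in seq_len(nrow(freqs))) {
    set.seed(.derive_seed(spec$seed, 5000L + i))
    acs[i] <- rbinom(1L, an, freqs$freq[i])
  }
  sites <- freqs |>
    dplyr::mutate(filter = "PASS", ac = acs, an = an,
                  mappability = 1, is_decoy = FALSE)
  mk_decoy <- function(k, kind) {
    base <- sites[(k - 1L) %% nrow(freqs) + 1L, ]
    base$pos <- base$pos + 100000L + k
    base$ac <- 1L
    if (kind == "nonpass") base$filter <- "RF" else base$mappability <- 0.8
    base$is_decoy <- TRUE
    base
  }
  if (decoy_nonpass > 0L) {
    sites <- dplyr::bind_rows(sites, purrr::map_dfr(seq_len(decoy_nonpass),
                                                    mk_decoy, kind = "nonpass"))
  }
  if (decoy_lowmap > 0L) {
    sites <- dplyr::bind_rows(sites, purrr::map_dfr(seq_len(decoy_lowmap),
                                                    mk_decoy, kind = "lowmap"))
  }
  annotations <- sites |>
    dplyr::transmute(.data$chrom, .data$pos, .data$ref, .data$alt, .data$gene,
                     consequence = "intron_variant", mappability = .data$mappability)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(dir, "sites.vcf")
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##reference=", build),
             "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
             "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                   collapse = "\t"))
    ord <- order(sites$chrom, sites$pos)
    body <- vapply(ord, function(i) {
      paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
              ".", sites$filter[i],
              paste0("AC=", sites$ac[i], ";AN=", sites$an[i])), collapse = "\t")
    }, "")
    writeLines(c(hdr, body), vcf_path)
    ann_path <- file.path(dir, "site_annotations.tsv")
    readr::write_tsv(annotations, ann_path)
    paths <- list(vcf = vcf_path, annotations = ann_path)
  }
  list(sites = sites, annotations = annotations, paths = paths)
}
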