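#' Run a pipeline stage with logged record counts
#'
#' Orchestrates the package stages over files on disk with one structured
#' log line per step (records in/out), so the filter and classification
#' cascade stays auditable. Subcommands:
#' \describe{
#'   \item{`simulate`}{generate a synthetic cohort (and sites file) under
#'     `config$out_dir`.}
#'   \item{`landscape`}{read a sites VCF + annotation TSV, apply the site
#'     filters, classify, and write Table-style summary TSVs.}
#'   \item{`profile`}{read a cohort VCF (+ annotations, + optional CYP2D6
#'     SV table), build per-sample profiles, and write one report/profile/
#'     card triple per sample.}
#'   \item{`score`}{score a CYP2D6 call-matrix TSV and write per-sample
#'     verdicts and per-caller totals.}
#' }
#'
#' @param config List with (depending on subcommand) `out_dir`, `build`,
#'   `vcf`, `annotations`, `sv_table`, `calls`, `seed`, `n_samples`,
#'   `min_mappability`, `require_pass`, `bundle_dir`.
#' @param subcommand One of `"simulate"`, `"landscape"`, `"profile"`,
#'   `"score"`.
#' @param quiet Suppress log lines.
#' @return The stage's main result, invisibly; artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, subcommand = c("simulate", "landscape",
                                                "profile", "score"),
                         quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  build <- config$build %||% "GRCh37"
  bundle <- load_bundle(config$bundle_dir)
  log <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  log(subcommand, "bundle %s, build %s", bundle$version, build)

  if (subcommand == "simulate") {
    spec <- cohort_spec(n_samples = config$n_samples %||% 100L,
                        seed = config$seed %||% stop("config$seed is required"))
    res <- generate_cohort(spec, bundle, dir = out_dir, build = build)
    log("simulate", "%d samples x %d variants -> %s",
        spec$n_samples, nrow(res$truth), res$paths$vcf)
    return(invisible(res))
  }

  if (subcommand == "landscape") {
    sites <- read_vcf(config$vcf %||% stop("config$vcf is required"),
                      mode = "sites", build = build)
    ann <- read_annotations(config$annotations %||% stop("config$annotations is required"))
    log("read", "%d site records", nrow(sites))
    if ("gene" %in% names(ann)) {
      sites <- dplyr::left_join(
        sites, dplyr::select(ann, "chrom", "pos", "ref", "alt", "gene"),
        by = c("chrom", "pos", "ref", "alt")
      )
    }
    filt <- apply_site_filters(sites, ann,
                               min_mappability = config$min_mappability %||% 1.0,
                               require_pass = config$require_pass %||% TRUE)
    kept <- filter_retained(filt)
    log("filter", "%d retained, %d excluded", nrow(kept), nrow(filt) - nrow(kept))
    cls <- classify_variants(kept, ann, bundle$panel, build = build)
    log("classify", "dpwg %d, lof %d, missense %d, other %d",
        sum(cls$category == "dpwg"), sum(cls$category == "lof"),
        sum(cls$category == "damaging_missense"), sum(cls$category == "other"))
    land <- gene_landscape(cls)
    summ <- summarize_cohort(cls)
    readr::write_tsv(land, file.path(out_dir, "landscape.tsv"))
    readr::write_tsv(summ, file.path(out_dir, "summary.tsv"))
    log("write", "landscape.tsv (%d rows), summary.tsv (%d rows)",
        nrow(land), nrow(summ))
    return(invisible(list(landscape = land, summary = summ, classified = cls)))
  }

  if (subcommand == "profile") {
    gts <- read_vcf(config$vcf %||% stop("config$vcf is required"),
                    mode = "cohort", build = build)
    ann <- if (!is.null(config$annotations)) read_annotations(config$annotations)
    sv <- if (!is.null(config$sv_table)) {
      readr::read_tsv(config$sv_table, comment = "#", show_col_types = FALSE)
    }
    log("read", "%d genotype records, %d samples",
        nrow(gts), dplyr::n_distinct(gts$sample))
    prof <- pgx_profile(gts, bundle, annotations = ann, sv_table = sv,
                        build = build)
    write_reports(prof, out_dir)
    log("write", "%d report/card triples", dplyr::n_distinct(prof$calls$sample))
    return(invisible(prof))
  }

  # score
  calls <- load_cyp2d6_calls(config$calls)
  res <- score_cyp2d6_calls(calls)
  readr::write_tsv(res$verdicts, file.path(out_dir, "verdicts.tsv"))
  readr::write_tsv(res$totals, file.path(out_dir, "totals.tsv"))
  for (i in seq_len(nrow(res$totals))) {
    log("score", "%s: %d/%d correct", res$totals$caller[i],
        res$totals$n_correct[i], res$totals$n_samples[i])
  }
  invisible(res)
}
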