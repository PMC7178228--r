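#' Loss-of-function test for one annotated variant
#'
#' A variant is LOF when it introduces a premature termination codon
#' (nonsense or frameshift, with or without expected nonsense-mediated
#' decay) or is a canonical splice-site SNV (intronic position within 1–2 bp
#' of an exon boundary) predicted in silico to alter splicing. When no
#' splice prediction is available, canonical +/-1–2 bp splice SNVs are
#' treated as splice-altering with a warning.
#'
#' @param consequence Consequence term (VEP/SnpEff-style:
#'   `stop_gained`, `frameshift_variant`, `splice_acceptor_variant`,
#'   `splice_donor_variant`, `missense_variant`, ...).
#' @param splice_pred Optional splice-prediction verdict for near-splice
#'   variants (`"altering"`/`"yes"`/`"D"` count as altering); `NA` if absent.
#' @param quiet Suppress the missing-splice-prediction warning.
#' @return A list with `lof` (logical) and `reason`
#'   (`"ptc"`, `"frameshift"`, `"splice"`, `NA`).
#' @export
is_lof <- function(consequence, splice_pred = NA, quiet = FALSE) {
  if (is.na(consequence) || !nzchar(consequence)) {
    return(list(lof = FALSE, reason = "unannotated"))
  }
  cons <- tolower(consequence)
  if (grepl("stop_gained|nonsense", cons)) return(list(lof = TRUE, reason = "ptc"))
  if (grepl("frameshift", cons)) return(list(lof = TRUE, reason = "frameshift"))
  if (grepl("splice_acceptor|splice_donor", cons)) {
    if (is.na(splice_pred)) {
      if (!quiet) {
        warning("no splice prediction for canonical splice-site variant; assuming altering",
                call. = FALSE)
      }
      return(list(lof = TRUE, reason = "splice"))
    }
    altering <- tolower(splice_pred) %in% c("altering", "yes", "d", "damaging", "true", "1")
    return(list(lof = altering, reason = if (altering) "splice" else NA_character_))
  }
  list(lof = FALSE, reason = NA_character_)
}

.predictor_cols <- c("fathmm", "fathmm_mkl", "mutation_assessor",
                     "mutation_taster", "polyphen2", "sift")
.damaging_values <- c("d", "damaging", "deleterious", "probably_damaging",
                      "disease_causing", "high", "medium")

#' Consensus-damaging missense test
#'
#' A missense variant counts as consensus-damaging only when all six
#' in-silico predictors (FATHMM, FATHMM-MKL, MutationAssessor,
#' MutationTaster, PolyPhen-2, SIFT) call it damaging/deleterious — a strict
#' conjunction; a missing verdict is never damaging.
#'
#' @param verdicts Named character vector or one-row data frame carrying the
#'   six predictor columns (`fathmm`, `fathmm_mkl`, `mutation_assessor`,
#'   `mutation_taster`, `polyphen2`, `sift`).
#' @return Logical scalar.
#' @export
is_consensus_damaging_missense <- function(verdicts) {
  if (is.data.frame(verdicts)) verdicts <- unlist(verdicts[1, , drop = TRUE])
  v <- verdicts[.predictor_cols]
  if (length(v) != 6L || anyNA(v)) return(FALSE)
  all(tolower(v) %in% .damaging_values)
}

#' Classify retained variants
#'
#' The classification cascade applied to every retained site, with
#' precedence DPWG panel > LOF > consensus-damaging missense > other:
#' \enumerate{
#'   \item a coordinate match against the panel gives category `dpwg`;
#'   \item otherwise LOF variants (see [is_lof()]) give `lof`;
#'   \item otherwise missense variants damaging by all six predictors give
#'     `damaging_missense`;
#'   \item everything else is `other`.
#' }
#' Novelty for LOF/missense variants is `known` when any database flag
#' (ClinVar drug response, HGMD FP/DFP/DM?/DM in drug-response context,
#' PharmGKB) is set, else `novel`; panel variants carry novelty `n_a`.
#' LOF/missense variants in HLA-B are classified `other` with reason
#' `hla_excluded` (short-read alignment ambiguity).
#'
#' @param records Retained site tibble with columns `chrom`, `pos`, `ref`,
#'   `alt` and a `gene` column (records outside panel genes keep their
#'   stated gene symbol).
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param panel A `pgx_panel`.
#' @param build Genome build of the coordinates.
#' @return `records` with columns `category`, `novelty`, `reason` and
#'   `star_label` (for panel hits) appended.
#' @export
classify_variants <- function(records, annotations, panel, build = "GRCh37") {
  stopifnot(is.data.frame(records))
  ann_cols <- unique(c("chrom", "pos", "ref", "alt", "consequence",
                       .predictor_cols, "splice_pred",
                       "clinvar_drug_response", "hgmd_class", "pharmgkb"))
  ann_cols <- intersect(ann_cols, names(annotations))
  rec <- dplyr::left_join(records,
                          dplyr::select(annotations, dplyr::all_of(ann_cols)),
                          by = c("chrom", "pos", "ref", "alt"))
  n <- nrow(rec)
  category <- character(n)
  novelty <- character(n)
  reason <- character(n)
  star <- rep(NA_character_, n)
  flag_set <- function(x) !is.na(x) & nzchar(x) & !tolower(x) %in% c("no", "false", "0", "na")
  known <- flag_set(rec$clinvar_drug_response %||% rep(NA_character_, n)) |
    (flag_set(rec$hgmd_class %||% rep(NA_character_, n)) &
       (toupper(rec$hgmd_class %||% "") %in% c("FP", "DFP", "DM?", "DM") |
          tolower(rec$hgmd_class %||% "") %in% c("yes", "true", "1"))) |
    flag_set(rec$pharmgkb %||% rep(NA_character_, n))
  for (i in seq_len(n)) {
    hit <- lookup_variant(panel, rec$chrom[i], rec$pos[i], rec$ref[i], rec$alt[i],
                          build = build)
    hit <- hit[hit$variant_kind %in% c("snv", "indel", "tag"), ]
    gene_i <- rec$gene[i] %||% NA_character_
    if (nrow(hit)) {
      category[i] <- "dpwg"
      novelty[i] <- "n_a"
      reason[i] <- "panel_match"
      star[i] <- hit$star_label[1]
      next
    }
    cons <- rec$consequence[i] %||% NA_character_
    lof <- is_lof(cons, rec$splice_pred[i] %||% NA, quiet = TRUE)
    damaging <- !is.na(cons) && grepl("missense", tolower(cons)) &&
      is_consensus_damaging_missense(rec[i, intersect(.predictor_cols, names(rec))])
    if ((lof$lof || damaging) && !is.na(gene_i) && gene_i == "HLA-B") {
      category[i] <- "other"
      novelty[i] <- "n_a"
      reason[i] <- "hla_excluded"
      next
    }
    if (lof$lof) {
      category[i] <- "lof"
      reason[i] <- lof$reason
    } else if (damaging) {
      category[i] <- "damaging_missense"
      reason[i] <- "six_of_six_damaging"
    } else {
      category[i] <- "other"
      reason[i] <- if (is.na(cons) || !nzchar(cons)) "unannotated" else "no_rule_hit"
    }
    novelty[i] <- if (category[i] == "other") "n_a" else {
      if (isTRUE(known[i])) "known" else "novel"
    }
  }
  rec$category <- category
  rec$novelty <- novelty
  rec$reason <- reason
  rec$star_label <- star
  rec
}
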