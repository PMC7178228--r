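#' Load the DPWG-style pharmacogene variant panel
#'
#' The bundled panel is a curated snapshot of the DPWG/PREPARE variant list:
#' 45 star-allele defining SNVs and indels in 11 pharmacogenes (CYP2B6,
#' CYP2C9, CYP2C19, CYP2D6, CYP3A5, DPYD, F5, SLCO1B1, TPMT, UGT1A1, VKORC1),
#' the HCP5 rs2395029 tag for HLA-B*57:01, and CYP2D6 structural-variant
#' slots (whole-gene deletion *5, duplication xN) whose alleles come from an
#' external SV caller. Every SNV/indel/tag entry carries coordinates on both
#' GRCh37 and GRCh38; indels are stored left-aligned in minimal VCF
#' representation.
#'
#' @param path Path to a panel TSV (columns `gene`, `star_label`, `rsid`,
#'   `chrom`, `pos_37`, `pos_38`, `ref`, `alt`, `hgvs_c`, `function_class`,
#'   `variant_kind`; `#` comment header lines allowed). Default: the bundled
#'   panel.
#' @param quiet Suppress the count report message.
#'
#' @return A tibble of class `pgx_panel`, one row per panel entry, with the
#'   bundle version in attribute `"bundle_version"`.
#'
#' @examples
#' panel <- load_panel(quiet = TRUE)
#' dplyr::count(panel, gene)
#' @export
load_panel <- function(path = NULL, quiet = FALSE) {
  path <- path %||% system.file("extdata", "dpwg", "panel_variants.tsv",
                                package = "pgxprofiler", mustWork = TRUE)
  if (!file.exists(path)) stop("panel file not found: ", path)
  content <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  if (length(content) <= 1L) stop("panel file is empty: ", path)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           pos_37 = readr::col_integer(),
                           pos_38 = readr::col_integer(),
                           .default = readr::col_character()
                         ))
  need <- c("gene", "star_label", "chrom", "pos_37", "pos_38", "ref", "alt",
            "function_class", "variant_kind")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) stop("panel file missing columns: ", paste(missing, collapse = ", "))
  validate_panel(tbl)
  version <- .file_version(path) %||% .bundle_version(dirname(path))
  if (!quiet) {
    n_si <- sum(tbl$variant_kind %in% c("snv", "indel"))
    message("panel loaded: ", n_si, " SNV/indel variants in ",
            dplyr::n_distinct(tbl$gene[tbl$variant_kind %in% c("snv", "indel")]),
            " genes (+", sum(tbl$variant_kind == "tag"), " tag, ",
            sum(tbl$variant_kind == "sv_slot"), " SV slots); bundle ", version)
  }
  structure(tbl, bundle_version = version, class = c("pgx_panel", class(tbl)))
}

.bundle_version <- function(dir) {
  vf <- file.path(dir, "VERSION")
  if (file.exists(vf)) readLines(vf, n = 1L) else "unversioned"
}

# bundle version stated in the file's own comment header, if any
.file_version <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  m <- grep("bundle_version:", hdr, value = TRUE)
  if (length(m)) trimws(sub(".*bundle_version:", "", m[1])) else NULL
}

validate_panel <- function(tbl) {
  dup <- duplicated(tbl[, c("gene", "star_label")])
  if (any(dup)) {
    stop("duplicate (gene, star_label) in panel: ",
         paste(unique(paste(tbl$gene[dup], tbl$star_label[dup])), collapse = ", "))
  }
  si <- tbl$variant_kind %in% c("snv", "indel", "tag")
  coords_bad <- si & (is.na(tbl$pos_37) | is.na(tbl$pos_38) | is.na(tbl$chrom) |
                        is.na(tbl$ref) | is.na(tbl$alt) | !nzchar(tbl$ref) | !nzchar(tbl$alt))
  if (any(coords_bad)) {
    stop("malformed coordinates for panel entries: ",
         paste(tbl$gene[coords_bad], tbl$star_label[coords_bad], collapse = ", "))
  }
  if (any(si & tbl$ref == tbl$alt)) stop("panel entries with ref == alt")
  classes <- c("no_function", "decreased", "normal", "increased", "unknown")
  if (!all(tbl$function_class %in% classes)) {
    stop("unknown function_class values: ",
         paste(setdiff(tbl$function_class, classes), collapse = ", "))
  }
  n_si <- sum(tbl$variant_kind %in% c("snv", "indel"))
  n_genes <- dplyr::n_distinct(tbl$gene[tbl$variant_kind %in% c("snv", "indel")])
  if (n_si != 45L || n_genes != 11L) {
    warning("panel has ", n_si, " SNV/indel variants in ", n_genes,
            " genes (bundled default: 45 in 11); proceeding with extended/reduced panel",
            call. = FALSE)
  }
  invisible(tbl)
}

#' Write a panel back to TSV
#'
#' Produces a file that [load_panel()] reads back content-identically
#' (column order and comment header normalised).
#'
#' @param panel A `pgx_panel` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  hdr <- c("# DPWG-style pharmacogene panel bundle (curated snapshot, user-extensible)",
           "# schema_version: 1",
           paste0("# bundle_version: ", attr(panel, "bundle_version") %||% "unversioned"))
  writeLines(hdr, path)
  readr::write_tsv(as.data.frame(panel), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Look up a panel variant by genomic coordinates
#'
#' Exact-match lookup after left-alignment/trimming to minimal
#' representation. Multi-allelic records must be decomposed by the caller.
#'
#' @param panel A `pgx_panel` tibble.
#' @param chrom,pos,ref,alt Coordinates of one biallelic variant (1-based,
#'   VCF convention).
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @return The matching panel row(s) as a tibble (zero rows if the site is
#'   not on the panel).
#' @export
lookup_variant <- function(panel, chrom, pos, ref, alt, build = c("GRCh37", "GRCh38")) {
  build <- match.arg(build)
  pos_col <- if (build == "GRCh37") "pos_37" else "pos_38"
  nn <- normalize_allele(pos, ref, alt)
  hit <- !is.na(panel[[pos_col]]) &
    .norm_chrom(panel$chrom) == .norm_chrom(chrom) &
    panel[[pos_col]] == nn$pos &
    panel$ref == nn$ref & panel$alt == nn$alt
  panel[hit, ]
}

#' Load the full guideline bundle
#'
#' Reads the panel plus its companion tables: diplotype-to-phenotype rules,
#' drug recommendations, the combined VKORC1/CYP2C9 anticoagulant dosing
#' table, star-combination definitions (e.g. CYP2B6 *9 + *4 = *6), and
#' function classes for CYP2D6 star alleles reported by SV callers.
#'
#' @param dir Bundle directory; default: the packaged `dpwg` bundle.
#' @return A list of class `pgx_bundle` with elements `panel`,
#'   `phenotype_rules`, `recommendations`, `anticoagulant`, `combinations`,
#'   `cyp2d6_functions`, and `version`.
#' @export
load_bundle <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", "dpwg", package = "pgxprofiler", mustWork = TRUE)
  rd <- function(f, ...) readr::read_tsv(file.path(dir, f), comment = "#",
                                         show_col_types = FALSE, ...)
  bundle <- list(
    panel = load_panel(file.path(dir, "panel_variants.tsv"), quiet = TRUE),
    phenotype_rules = rd("phenotype_rules.tsv"),
    recommendations = rd("recommendations.tsv"),
    anticoagulant = rd("anticoagulant_dosing.tsv"),
    combinations = rd("star_combinations.tsv"),
    cyp2d6_functions = rd("cyp2d6_allele_function.tsv",
                          col_types = readr::cols(.default = readr::col_character())),
    version = .bundle_version(dir)
  )
  structure(bundle, class = "pgx_bundle")
}

#' Function class of a star allele
#'
#' `*1` is the wildtype/normal haplotype; other labels resolve through the
#' panel (for that gene) or, for CYP2D6 SV-caller labels, through the
#' bundled CYP2D6 allele-function table. Unresolvable labels are `unknown`.
#'
#' @param gene Gene symbol.
#' @param label Star-allele label, with or without the leading `*`;
#'   CYP2D6 haplotype strings may carry tandems (`*68+*4`) and copy counts
#'   (`*2x2`).
#' @param bundle A `pgx_bundle`.
#' @return Character scalar in `no_function`, `decreased`, `normal`,
#'   `increased`, `unknown`.
#' @export
allele_function <- function(gene, label, bundle) {
  stopifnot(inherits(bundle, "pgx_bundle"))
  lab <- sub("^\\*", "", label)
  if (is.na(lab) || lab %in% c("?", "")) return("unknown")
  if (lab == "1") return("normal")
  # tandem/copy-count CYP2D6 haplotype: most functional component wins,
  # >=2 copies of a normal allele count as increased
  if (gene == "CYP2D6" && grepl("[+x×]", lab)) {
    comps <- parse_diplotype(paste0("*", lab, "/*1"))
    comps <- comps[comps$haplotype == 1L, ]
    fns <- vapply(comps$label, function(l) allele_function("CYP2D6", l, bundle), "")
    ord <- c(no_function = 0, decreased = 1, normal = 2, increased = 3, unknown = NA)
    if (anyNA(ord[fns])) return("unknown")
    best_i <- which.max(ord[fns])
    if (fns[[best_i]] == "normal" && comps$copies[best_i] >= 2L) return("increased")
    return(unname(fns[best_i]))
  }
  hit <- bundle$panel$gene == gene & sub("^\\*", "", bundle$panel$star_label) == lab
  if (any(hit)) return(bundle$panel$function_class[which(hit)[1]])
  if (gene == "CYP2D6") {
    f <- bundle$cyp2d6_functions$function_class[bundle$cyp2d6_functions$label == lab]
    if (length(f)) return(f[1])
  }
  "unknown"
}

#' Translate a diplotype to a metabolizer phenotype
#'
#' Explicit star-pair rules (carrier-style genes F5, VKORC1, HCP5) take
#' precedence; otherwise the unordered pair of allele function classes is
#' matched against the generic DPWG-convention class rules (two no-function
#' alleles give PM, two increased-function alleles give UM, etc.). If either
#' haplotype's function is unknown the phenotype is `unknown`.
#'
#' @param gene Gene symbol (must be covered by the bundle).
#' @param diplotype Diplotype string `"*a/*b"`, or length-2 character vector
#'   of allele labels.
#' @param bundle A `pgx_bundle` (default: the packaged bundle).
#' @return A list with `phenotype` and `flag` (`NA` or
#'   `"unknown_allele_function"`).
#'
#' @examples
#' b <- load_bundle()
#' translate_phenotype("CYP2C19", "*2/*2", b)$phenotype   # "PM"
#' translate_phenotype("CYP2C19", "*17/*17", b)$phenotype # "UM"
#' @export
translate_phenotype <- function(gene, diplotype, bundle = load_bundle()) {
  stopifnot(inherits(bundle, "pgx_bundle"))
  known_genes <- union(bundle$panel$gene, bundle$phenotype_rules$gene)
  if (!gene %in% known_genes) stop("gene not covered by phenotype rules: ", gene)
  alleles <- if (length(diplotype) == 2L) diplotype else {
    strsplit(diplotype, "/", fixed = TRUE)[[1]]
  }
  if (length(alleles) != 2L) stop("diplotype must have two haplotypes: ", diplotype)
  labs <- sort(sub("^\\*", "", alleles))
  star <- bundle$phenotype_rules[bundle$phenotype_rules$kind == "star" &
                                   bundle$phenotype_rules$gene == gene, ]
  if (nrow(star)) {
    key <- paste(sort(labs), collapse = "|")
    rule_key <- vapply(seq_len(nrow(star)), function(i) {
      paste(sort(sub("^\\*", "", c(star$allele1[i], star$allele2[i]))), collapse = "|")
    }, "")
    m <- which(rule_key == key)
    if (length(m)) return(list(phenotype = star$phenotype[m[1]], flag = NA_character_))
  }
  fns <- vapply(paste0("*", labs), function(l) allele_function(gene, l, bundle), "")
  if (any(fns == "unknown")) {
    return(list(phenotype = "unknown", flag = "unknown_allele_function"))
  }
  cls <- bundle$phenotype_rules[bundle$phenotype_rules$kind == "class", ]
  key <- paste(sort(fns), collapse = "|")
  rule_key <- vapply(seq_len(nrow(cls)), function(i) {
    paste(sort(c(cls$allele1[i], cls$allele2[i])), collapse = "|")
  }, "")
  m <- which(rule_key == key)
  if (!length(m)) stop("no phenotype rule for class pair: ", key)
  list(phenotype = cls$phenotype[m[1]], flag = NA_character_)
}
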