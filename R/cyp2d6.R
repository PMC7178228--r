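#' CYP2D6 diplotype grammar and concordance scoring
#'
#' CYP2D6 genotypes from short-read WGS callers are written as diplotype
#' strings combining SNV/indel-defined star alleles with structural alleles:
#' whole-gene deletions (`*5`), duplications (`*2x2`, also printed `*2×2`),
#' and CYP2D6--CYP2D7 hybrid tandems (`*68+*4`, one haplotype carrying a
#' hybrid plus a conventional allele). Consensus genotypes from reference
#' materials additionally use parenthesized segments such as `(*36)+*10` for
#' components some assays report and others do not.
#'
#' `parse_diplotype()` turns such a string into a tibble of allele
#' components; `allele_multiset()` flattens it, phase-insensitively, into a
#' multiset of star-allele labels; `score_call()` compares a caller's
#' diplotype with a consensus genotype by multiset equality.
#'
#' @name cyp2d6-concordance
NULL

# grammar: DIP := HAP "/" HAP ; HAP := COMP ("+" COMP)* ;
# COMP := ["("] "*" LABEL ["x" N] [")"]
.dip_component_rx <- "^\\(?\\*([A-Za-z0-9]+?)(?:x([0-9]+))?\\)?$"

#' Parse a CYP2D6 diplotype string
#'
#' @param text Diplotype string, e.g. `"*1/*4"`, `"*2x2/*71"`,
#'   `"*1/*36x2+*10"`, or (consensus notation) `"*3/(*68)+*4"`. The
#'   multiplication sign may be written `x` or `×`.
#'
#' @return A tibble of class `pgx_diplotype` with one row per allele
#'   component and columns `haplotype` (1 or 2), `label` (star-allele label
#'   without the `*`), `copies` (integer copy count from `xN`, default 1) and
#'   `optional` (`TRUE` for parenthesized consensus segments). The original
#'   string is kept in the `"text"` attribute.
#'
#' @examples
#' parse_diplotype("*2x2/*71")
#' parse_diplotype("(*36+)*10/*41")
#' @export
parse_diplotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  raw <- text
  s <- gsub("×", "x", trimws(text))
  s <- gsub("\\s+", "", s)
  # consensus writes tandem-attached optional segments as "(*36+)*10";
  # normalise the trailing "+" out of the parentheses: "(*36)+*10"
  s <- gsub("\\((\\*[A-Za-z0-9x]+)\\+\\)", "(\\1)+", s)
  haps <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(haps) != 2L || any(!nzchar(haps))) {
    stop("malformed diplotype (expected two '/'-separated haplotypes): ", raw)
  }
  parse_hap <- function(hap, idx) {
    comps <- strsplit(hap, "+", fixed = TRUE)[[1]]
    if (!length(comps) || any(!nzchar(comps))) {
      stop("malformed haplotype '", hap, "' in: ", raw)
    }
    m <- regmatches(comps, regexec(.dip_component_rx, comps))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) stop("malformed allele component '", comps[bad][1], "' in: ", raw)
    tibble::tibble(
      haplotype = idx,
      label = vapply(m, `[`, "", 2L),
      copies = {
        n <- vapply(m, `[`, "", 3L)
        as.integer(ifelse(nzchar(n), n, "1"))
      },
      optional = startsWith(comps, "(")
    )
  }
  out <- dplyr::bind_rows(parse_hap(haps[1], 1L), parse_hap(haps[2], 2L))
  if (any(out$copies < 1L)) stop("copy count must be >= 1 in: ", raw)
  structure(out, text = raw, class = c("pgx_diplotype", class(out)))
}

#' Render a parsed diplotype back to its string form
#'
#' Inverse of [parse_diplotype()] up to notation normalisation
#' (`×` becomes `x`, optional segments are written `(*a)+...`).
#'
#' @param parsed A `pgx_diplotype` tibble.
#' @return A single diplotype string.
#' @export
render_diplotype <- function(parsed) {
  stopifnot(inherits(parsed, "pgx_diplotype"))
  one <- function(df) {
    comp <- paste0("*", df$label, ifelse(df$copies > 1L, paste0("x", df$copies), ""))
    comp <- ifelse(df$optional, paste0("(", comp, ")"), comp)
    paste(comp, collapse = "+")
  }
  paste(one(parsed[parsed$haplotype == 1L, ]), one(parsed[parsed$haplotype == 2L, ]),
        sep = "/")
}

#' Expand a diplotype into a phase-insensitive allele multiset
#'
#' Copy counts contribute multiple copies; haplotype membership and component
#' order are discarded. Parenthesized (optional-annotated) consensus segments
#' are included: concordance scoring treats them as required, which is the
#' reading under which published tool-comparison tallies are reproduced.
#'
#' @param parsed A `pgx_diplotype` tibble, or a diplotype string.
#' @param include_optional Include parenthesized components (default `TRUE`).
#' @return Sorted character vector of star-allele labels (without `*`), one
#'   element per allele copy.
#'
#' @examples
#' allele_multiset("*1/*36x2+*10")    # "1"  "10" "36" "36"
#' allele_multiset("*1+*36/*36+*10")  # same multiset, different phase
#' @export
allele_multiset <- function(parsed, include_optional = TRUE) {
  if (is.character(parsed)) parsed <- parse_diplotype(parsed)
  stopifnot(inherits(parsed, "pgx_diplotype"))
  df <- if (include_optional) parsed else parsed[!parsed$optional, ]
  sort(rep(df$label, df$copies))
}

#' Score one caller diplotype against a consensus genotype
#'
#' A call is correct when its allele multiset equals the consensus multiset:
#' phase (the assignment of alleles to haplotypes) is ignored, so a caller
#' that finds all the right alleles in the wrong arrangement still scores
#' correct. Copy counts matter (`*2x2` is two `*2` alleles). Suballele
#' labels are compared at printed granularity (`*13C` does not match `*13`).
#'
#' @param call Caller diplotype (string or `pgx_diplotype`).
#' @param consensus Consensus genotype (string or `pgx_diplotype`).
#' @param alternates Optional list of length-2 character vectors of
#'   label equivalences accepted for this sample, e.g. `list(c("1","106"))`
#'   for a consensus `*1` manually confirmed as `*106`. Symmetric.
#' @param note Optional caller annotation: `"hybrid_68"` appends a `*68`
#'   hybrid the caller reported alongside its diplotype; `"dup_unassigned"`
#'   (a duplication flagged but not assigned) contributes nothing;
#'   `"no_phase"` (no phased major solution) scores incorrect outright.
#'
#' @return A list with elements `correct` (logical) and `reason` (character:
#'   `"multiset_equal"`, `"multiset_mismatch"`, or `"no_major_solution"`).
#' @export
score_call <- function(call, consensus, alternates = NULL, note = NULL) {
  note <- note %||% ""
  if (identical(note, "no_phase")) {
    return(list(correct = FALSE, reason = "no_major_solution"))
  }
  cm <- allele_multiset(call)
  if (identical(note, "hybrid_68")) cm <- sort(c(cm, "68"))
  gm <- allele_multiset(consensus)
  canon <- function(labels) {
    for (pair in alternates %||% list()) {
      stopifnot(length(pair) == 2L)
      rep_to <- sort(pair)[1]
      labels[labels %in% pair] <- rep_to
    }
    sort(labels)
  }
  ok <- identical(canon(cm), canon(gm))
  list(correct = ok, reason = if (ok) "multiset_equal" else "multiset_mismatch")
}

#' Load the bundled GeT-RM 2019 CYP2D6 call matrix
#'
#' Twenty-one reference WGS samples with the GeT-RM 2019 consensus CYP2D6
#' genotype and the diplotype called by each of three short-read callers
#' (Astrolabe, Aldy, Stargazer), including the footnote annotations needed
#' for faithful scoring (hybrid alleles reported alongside a call,
#' unassigned duplication flags, an unphased call, and one manually
#' confirmed allele equivalence).
#'
#' @param path Optional path to a call-matrix TSV in the same layout
#'   (columns `sample`, `consensus`, one column per caller, `<caller>_note`,
#'   `alternates`); defaults to the packaged table.
#' @return A tibble, one row per sample.
#' @export
load_cyp2d6_calls <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "getrm", "cyp2d6_getrm_2019_calls.tsv",
                package = "pgxprofiler", mustWork = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample", "consensus")
  if (!all(need %in% names(tbl))) {
    stop("call matrix must have at least columns: ", paste(need, collapse = ", "))
  }
  tbl
}

.parse_alternates <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  lapply(strsplit(s, ";", fixed = TRUE)[[1]],
         function(p) strsplit(p, "=", fixed = TRUE)[[1]])
}

#' Score a full caller-by-sample call matrix
#'
#' Applies [score_call()] to every caller column of a call matrix and
#' tallies correct calls per caller.
#'
#' @param calls Call-matrix tibble as returned by [load_cyp2d6_calls()].
#'   Caller columns are every column other than `sample`, `consensus`,
#'   `alternates` and `*_note`.
#' @return An object of class `pgx_concordance`: a list with `verdicts`
#'   (tibble: sample, caller, call, correct, reason) and `totals` (tibble:
#'   caller, n_correct, n_samples). `tidy()` and `glance()` methods return
#'   these tibbles.
#'
#' @examples
#' res <- score_cyp2d6_calls(load_cyp2d6_calls())
#' glance(res)
#' @export
score_cyp2d6_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  reserved <- c("sample", "consensus", "alternates")
  callers <- setdiff(names(calls), c(reserved, grep("_note$", names(calls), value = TRUE)))
  if (!length(callers)) stop("no caller columns found in call matrix")
  verdicts <- purrr::map_dfr(callers, function(cl) {
    note_col <- paste0(cl, "_note")
    purrr::pmap_dfr(
      list(calls$sample, calls$consensus, calls[[cl]],
           if (note_col %in% names(calls)) calls[[note_col]] else NA_character_,
           if ("alternates" %in% names(calls)) calls$alternates else NA_character_),
      function(smp, cons, call, note, alt) {
        res <- score_call(call, cons,
                          alternates = .parse_alternates(alt),
                          note = if (is.na(note)) NULL else note)
        tibble::tibble(sample = smp, caller = cl, call = call,
                       consensus = cons, correct = res$correct, reason = res$reason)
      }
    )
  })
  totals <- verdicts |>
    dplyr::group_by(.data$caller) |>
    dplyr::summarise(n_correct = sum(.data$correct),
                     n_samples = dplyr::n(), .groups = "drop")
  structure(list(verdicts = verdicts, totals = totals), class = "pgx_concordance")
}

#' @export
print.pgx_concordance <- function(x, ...) {
  cat("CYP2D6 diplotype concordance (", x$totals$n_samples[1], " samples)\n", sep = "")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("  %-10s %d/%d correct\n", x$totals$caller[i],
                x$totals$n_correct[i], x$totals$n_samples[i]))
  }
  invisible(x)
}

#' @export
#' @rdname score_cyp2d6_calls
#' @method tidy pgx_concordance
#' @param x A `pgx_concordance` object.
#' @param ... Unused.
tidy.pgx_concordance <- function(x, ...) x$verdicts

#' @export
#' @rdname score_cyp2d6_calls
#' @method glance pgx_concordance
glance.pgx_concordance <- function(x, ...) {
  tidyr::pivot_wider(x$totals[, c("caller", "n_correct")],
                     names_from = "caller", values_from = "n_correct") |>
    dplyr::mutate(n_samples = x$totals$n_samples[1])
}
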