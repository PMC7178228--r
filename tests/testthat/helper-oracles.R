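# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Continuity-corrected Wilson limits by numeric root finding on the score
# equation |p_hat - p| = z*sqrt(p(1-p)/n) + 1/(2n)
oracle_wilson_cc <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  low <- if (x == 0) 0 else {
    uniroot(function(q) p - q - 1 / (2 * n) - z * sqrt(q * (1 - q) / n),
            c(0, p), tol = 1e-12)$root
  }
  high <- if (x == n) 1 else {
    uniroot(function(q) q - p - 1 / (2 * n) - z * sqrt(q * (1 - q) / n),
            c(p, 1), tol = 1e-12)$root
  }
  c(low = low, high = high)
}

# Brute-force multiset comparison by per-label occurrence counting (no
# sorting; counts every distinct label on both sides)
oracle_multiset_equal <- function(a, b) {
  labs <- unique(c(a, b))
  for (l in labs) {
    if (sum(a == l) != sum(b == l)) return(FALSE)
  }
  TRUE
}

# Brute-force MAF binning from first principles
oracle_maf_bin <- function(ac, an) {
  maf <- min(ac, an - ac) / an
  if (maf < 0.001) "rare" else if (maf <= 0.05) "low" else "common"
}

# Random diplotype string over a small allele pool (copies and tandems)
random_diplotype <- function(pool = c("1", "2", "4", "5", "10", "36", "68",
                                      "13C", "4N"),
                             max_components = 2L, max_copies = 2L) {
  hap <- function() {
    k <- sample.int(max_components, 1L)
    comps <- vapply(seq_len(k), function(i) {
      lab <- sample(pool, 1L)
      cp <- sample.int(max_copies, 1L)
      paste0("*", lab, if (cp > 1L) paste0("x", cp))
    }, "")
    paste(comps, collapse = "+")
  }
  paste(hap(), hap(), sep = "/")
}

# Minimal inline VCF writer for hand-built test records
write_test_vcf <- function(path, rows, samples = NULL, build = "GRCh37") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##reference=", build),
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (!is.null(samples)) c("FORMAT", samples)),
                 collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}
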