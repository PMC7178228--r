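# shared internal helpers

# variant key used to join sites, annotations and panel entries
.variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# strip a leading "chr" so GRCh37/38-style contig names compare equal
.norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# Left-align and trim a ref/alt pair to minimal representation.
# Plain SNVs pass through; shared suffix then shared prefix are removed,
# keeping the VCF convention of one anchor base for indels.
normalize_allele <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  r <- strsplit(toupper(ref), "")[[1]]
  a <- strsplit(toupper(alt), "")[[1]]
  # trim common suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim common prefix, advancing pos, but keep an anchor base for indels
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# vectorised wrapper returning a tibble
normalize_alleles <- function(pos, ref, alt) {
  out <- purrr::pmap(list(pos, ref, alt), normalize_allele)
  tibble::tibble(
    pos = vapply(out, function(x) x$pos, 1L),
    ref = vapply(out, function(x) x$ref, ""),
    alt = vapply(out, function(x) x$alt, "")
  )
}

# deterministic sub-seed derivation; keeps results in 32-bit signed range
.derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587 + 1
}
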