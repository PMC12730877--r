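# Independent brute-force implementations of the defining codon-usage
# formulas, written as plain loops straight from the definitions. They stay
# deliberately separate from the package's code paths and serve as oracles.

STANDARD_CODE <- Biostrings::GENETIC_CODE
ALL_SENSE <- sort(names(STANDARD_CODE)[STANDARD_CODE != "*"])

# RSCU(c) = observed count / (family total / family size); NA for empty
# families (including single-codon families Met/Trp when absent)
oracle_rscu <- function(counts) {
  out <- setNames(rep(NA_real_, length(ALL_SENSE)), ALL_SENSE)
  for (aa in unique(STANDARD_CODE[ALL_SENSE])) {
    fam <- ALL_SENSE[STANDARD_CODE[ALL_SENSE] == aa]
    total <- 0
    for (cod in fam) total <- total + counts[[cod]]
    if (total == 0) next
    for (cod in fam) {
      out[[cod]] <- counts[[cod]] / (total / length(fam))
    }
  }
  out
}

# Wright's ENC: per-family corrected homozygosity, averaged within each
# degeneracy class, F3 imputed as (F2+F4)/2 when Ile is unobserved
oracle_enc <- function(counts) {
  fam_of <- split(ALL_SENSE, STANDARD_CODE[ALL_SENSE])
  deg <- sapply(fam_of, length)
  fhat <- list()
  for (aa in names(fam_of)) {
    n <- 0; ss <- 0
    for (cod in fam_of[[aa]]) n <- n + counts[[cod]]
    if (n <= 1) { fhat[[aa]] <- NA_real_; next }
    for (cod in fam_of[[aa]]) ss <- ss + (counts[[cod]] / n)^2
    fhat[[aa]] <- (n * ss - 1) / (n - 1)
  }
  class_mean <- function(k) {
    vals <- unlist(fhat[names(deg)[deg == k]])
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6)) || any(c(f2, f3, f4, f6) <= 0)) {
    return(NA_real_)
  }
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# random small codon-count configuration (counts as a plain named list so
# the oracles never touch package objects)
random_counts <- function(max_count = 30) {
  x <- as.list(setNames(
    sample(0:max_count, length(ALL_SENSE), replace = TRUE), ALL_SENSE))
  x
}

counts_list_to_obj <- function(x) {
  codon_counts(unlist(x))
}

# write a small FASTA file and return its path
write_fasta_fixture <- function(entries, dir = tempdir()) {
  path <- tempfile(fileext = ".fa", tmpdir = dir)
  lines <- character(0)
  for (nm in names(entries)) {
    lines <- c(lines, paste0(">", nm), entries[[nm]])
  }
  writeLines(lines, path)
  path
}

# a syntactically clean CDS: ATG + given sense codons + stop
make_cds <- function(codons, stop_codon = "TAA") {
  paste0("ATG", paste(codons, collapse = ""), stop_codon)
}
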