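#' Count codons of an in-frame coding sequence
#'
#' Non-overlapping triplets are counted from the first position. A terminal
#' stop codon is recorded separately and excluded from the sense-codon total;
#' internal stops (which should not occur after quality filtering) are also
#' tallied in \code{stop_counts} with a warning.
#'
#' @param sequence In-frame CDS string over A/C/G/T, length divisible by 3.
#' @return A \code{codon_counts} object: list with \code{counts} (named
#'   integer vector over the 61 sense codons), \code{stop_counts} (named
#'   integer vector over TAA/TAG/TGA) and \code{n_codons} (total sense-codon
#'   count).
#' @examples
#' count_codons("ATGGCTGCTTAA")
#' @export
count_codons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) %% 3L != 0L) {
    stop("sequence length ", nchar(sequence), " is not divisible by 3")
  }
  cods <- codon_split(sequence)
  sense <- table(factor(cods, levels = SENSE_CODONS))
  stops <- table(factor(cods, levels = STOP_CODONS))
  n_internal <- sum(cods[-length(cods)] %in% STOP_CODONS)
  if (n_internal > 0L) {
    warning(n_internal, " internal stop codon(s) found; counted in stop_counts")
  }
  new_codon_counts(as.integer(sense), as.integer(stops))
}

new_codon_counts <- function(sense, stops = integer(3)) {
  counts <- as.numeric(sense)
  names(counts) <- SENSE_CODONS
  stop_counts <- as.numeric(stops)
  names(stop_counts) <- STOP_CODONS
  structure(
    list(counts = counts, stop_counts = stop_counts,
         n_codons = sum(counts)),
    class = "codon_counts"
  )
}

#' Build a codon_counts object from a named count vector
#'
#' Convenience constructor for synthetic count configurations. Unlisted sense
#' codons get count zero; stop codons may be included and are routed to
#' \code{stop_counts}.
#'
#' @param x Named numeric vector of non-negative codon counts.
#' @return A \code{codon_counts} object.
#' @export
codon_counts <- function(x) {
  stopifnot(!is.null(names(x)), all(x >= 0))
  bad <- setdiff(names(x), c(SENSE_CODONS, STOP_CODONS))
  if (length(bad)) stop("unknown codons: ", paste(bad, collapse = ", "))
  sense <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  stops <- stats::setNames(numeric(length(STOP_CODONS)), STOP_CODONS)
  is_stop <- names(x) %in% STOP_CODONS
  sense[names(x)[!is_stop]] <- x[!is_stop]
  stops[names(x)[is_stop]] <- x[is_stop]
  new_codon_counts(sense, stops)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts:", x$n_codons, "sense codons,",
      sum(x$stop_counts), "stop codon(s)\n")
  used <- x$counts[x$counts > 0]
  if (length(used)) print(utils::head(sort(used, decreasing = TRUE), 10L))
  invisible(x)
}

#' Pool codon counts over genes
#'
#' @param counts_list List of \code{codon_counts} objects.
#' @return A single \code{codon_counts} with element-wise summed counts.
#' @export
pool_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L)
  sense <- Reduce(`+`, lapply(counts_list, `[[`, "counts"))
  stops <- Reduce(`+`, lapply(counts_list, `[[`, "stop_counts"))
  new_codon_counts(sense, stops)
}

#' Amino-acid composition from codon counts
#'
#' Percentage of each of the 20 standard amino acids among translated sense
#' codons (stop codons excluded). Percentages sum to 100.
#'
#' @param counts A \code{codon_counts} object.
#' @return Named numeric vector of 20 percentages.
#' @export
aa_composition <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (counts$n_codons == 0) stop("no sense codons: composition undefined")
  by_aa <- tapply(counts$counts, CODON_AA[names(counts$counts)], sum)
  out <- stats::setNames(numeric(length(AA_LETTERS)), AA_LETTERS)
  out[names(by_aa)] <- by_aa
  100 * out / counts$n_codons
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of degeneracy k with family total N
#' is count(c) / (N / k): the observed frequency divided by the frequency
#' expected under equal synonymous usage. Values of 1 indicate unbiased use;
#' the family maximum equals the degeneracy. Families with zero counts yield
#' \code{NA} (undefined, not zero). The single-codon families Met and Trp are
#' reported as 1 when present. Codons with RSCU above \code{over} are flagged
#' overrepresented; below \code{under}, underrepresented.
#'
#' @param counts A \code{codon_counts} object.
#' @param over,under Flagging thresholds (defaults 1.6 and 0.6).
#' @return List with \code{values} (named numeric over 61 sense codons, NA
#'   where undefined) and \code{flags} (character: "overrepresented",
#'   "underrepresented", "neutral" or NA), class \code{rscu_vector}.
#' @export
rscu <- function(counts, over = 1.6, under = 0.6) {
  stopifnot(inherits(counts, "codon_counts"), over > under)
  values <- stats::setNames(rep(NA_real_, length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in names(AA_FAMILIES)) {
    fam <- AA_FAMILIES[[aa]]
    N <- sum(counts$counts[fam])
    if (N == 0) next
    k <- length(fam)
    values[fam] <- counts$counts[fam] / (N / k)
  }
  flags <- ifelse(is.na(values), NA_character_,
                  ifelse(values > over, "overrepresented",
                         ifelse(values < under, "underrepresented", "neutral")))
  structure(list(values = values, flags = flags, over = over, under = under),
            class = "rscu_vector")
}

#' @export
print.rscu_vector <- function(x, ...) {
  cat("RSCU over 61 sense codons;",
      sum(x$flags == "overrepresented", na.rm = TRUE), "overrepresented (>",
      x$over, "),", sum(x$flags == "underrepresented", na.rm = TRUE),
      "underrepresented (<", x$under, ")\n")
  invisible(x)
}

# positional GC fractions from pooled sense-codon counts
gc_from_counts <- function(counts) {
  n <- counts$n_codons
  if (n == 0) stop("no sense codons: positional GC undefined")
  gc1 <- sum(counts$counts[CODON_GC1]) / n
  gc2 <- sum(counts$counts[CODON_GC2]) / n
  gc3 <- sum(counts$counts[CODON_GC3]) / n
  list(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2)
}

#' Positional GC content of a coding sequence
#'
#' Fraction of G or C at each codon position among sense codons; a terminal
#' stop codon is excluded first. \code{gc12} is the mean of \code{gc1} and
#' \code{gc2}, the y-axis of a neutrality plot.
#'
#' @param sequence In-frame CDS string, length divisible by 3.
#' @return List with \code{gc1}, \code{gc2}, \code{gc3}, \code{gc12}.
#' @export
positional_gc <- function(sequence) {
  gc_from_counts(suppressWarnings(count_codons(sequence)))
}

#' Corrected codon homozygosity of one synonymous family
#'
#' Wright's bias-corrected estimator: with family total n and observed codon
#' proportions p, F = (n * sum(p^2) - 1) / (n - 1). Undefined (NA) when
#' n <= 1.
#'
#' @param family_counts Non-negative counts of the codons of one family.
#' @return A fraction in [0, 1], or NA.
#' @export
codon_homozygosity <- function(family_counts) {
  if (any(family_counts < 0)) stop("negative counts")
  n <- sum(family_counts)
  if (n <= 1) return(NA_real_)
  p <- family_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons (ENC)
#'
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk is the mean corrected
#' homozygosity (\code{\link{codon_homozygosity}}) over the families of
#' degeneracy k with at least two counted codons, and the constant 2 covers
#' Met and Trp. ENC ranges from 20 (one codon used per amino acid) to 61
#' (fully even synonymous usage); estimates above 61 from sampling noise are
#' capped at 61, matching common practice. If no three-fold family (Ile) is
#' observed, F3 is imputed as (F2 + F4)/2; if any other degeneracy class has
#' no defined family, or a class mean homozygosity is zero, ENC is NA.
#'
#' @param counts A \code{codon_counts} object.
#' @return ENC in [20, 61], or NA when undefined.
#' @export
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  fbar <- vapply(ENC_CLASSES, function(aas) {
    f <- vapply(aas, function(aa) {
      codon_homozygosity(counts$counts[AA_FAMILIES[[aa]]])
    }, numeric(1))
    f <- f[!is.na(f)]
    if (length(f) == 0L) NA_real_ else mean(f)
  }, numeric(1))
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (anyNA(fbar) || any(fbar <= 0)) return(NA_real_)
  value <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] +
    5 / fbar[["4"]] + 3 / fbar[["6"]]
  min(value, 61)
}

#' Per-gene codon-usage metrics
#'
#' @param genes Gene table of quality-passed CDS.
#' @return \code{data.frame} with gene_id, genome_id, n_codons, gc1, gc2,
#'   gc3, gc12 and enc (NA where undefined) per gene.
#' @export
gene_metrics <- function(genes) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    cc <- suppressWarnings(count_codons(genes$sequence[i]))
    gc <- gc_from_counts(cc)
    data.frame(gene_id = genes$gene_id[i], genome_id = genes$genome_id[i],
               n_codons = cc$n_codons, gc1 = gc$gc1, gc2 = gc$gc2,
               gc3 = gc$gc3, gc12 = gc$gc12, enc = enc(cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide codon usage profile from pooled counts
#'
#' Pools codon counts over all genes and computes amino-acid composition,
#' RSCU, positional GC and ENC on the pooled ("totals") counts — weighting
#' genes by their length, not averaging per-gene values.
#'
#' @param genes Gene table of quality-passed CDS (single genome expected).
#' @param genome_id Identifier for the profile; defaults to the (unique)
#'   genome_id of \code{genes}.
#' @param group Optional group label.
#' @param ... Passed to \code{\link{rscu}} (thresholds).
#' @return A \code{genome_profile} object: list with genome_id, group,
#'   n_genes, counts (pooled \code{codon_counts}), aa, rscu, gc (positional
#'   GC list) and enc.
#' @export
genome_profile <- function(genes, genome_id = NULL, group = NA_character_,
                           ...) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0L) stop("empty gene set: no profile")
  if (is.null(genome_id)) genome_id <- unique(genes$genome_id)[1]
  pooled <- pool_counts(lapply(genes$sequence, function(s) {
    suppressWarnings(count_codons(s))
  }))
  structure(
    list(genome_id = genome_id, group = group, n_genes = nrow(genes),
         counts = pooled, aa = aa_composition(pooled),
         rscu = rscu(pooled, ...), gc = gc_from_counts(pooled),
         enc = enc(pooled)),
    class = "genome_profile"
  )
}

#' @export
print.genome_profile <- function(x, ...) {
  cat("genome_profile:", x$genome_id,
      if (!is.na(x$group)) paste0("(", x$group, ")") else "", "\n")
  cat("  genes:", x$n_genes, " codons:", x$counts$n_codons, "\n")
  cat(sprintf("  GC3: %.3f  GC12: %.3f  ENC: %.2f\n",
              x$gc$gc3, x$gc$gc12, x$enc))
  invisible(x)
}
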