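#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least-squares fit of per-gene GC12 (mean GC of codon positions 1
#' and 2) on per-gene GC3. Under pure mutational pressure the third position
#' drifts with the first two and the slope approaches 1; selection on codon
#' usage flattens the slope toward 0 or removes the correlation altogether.
#' The selective constraint is summarized as
#' \code{selection_pct = (1 - |slope|) * 100}. When the correlation is not
#' significant at \code{alpha}, mutation leaves no measurable footprint and
#' the fit is reported as selection-dominated (\code{selection_pct = 100})
#' with \code{non_significant = TRUE}.
#'
#' @param per_gene \code{data.frame} with numeric columns \code{gc3} and
#'   \code{gc12} (one row per gene), e.g. from \code{\link{gene_metrics}}.
#' @param alpha Significance threshold for the slope test (default 0.01).
#' @return A \code{neutrality_fit} object: slope, intercept, r (Pearson),
#'   p_value (two-sided test of zero slope), n_genes, abs_slope,
#'   selection_pct, non_significant, alpha.
#' @export
neutrality_fit <- function(per_gene, alpha = 0.01) {
  stopifnot(is.data.frame(per_gene),
            all(c("gc3", "gc12") %in% names(per_gene)))
  ok <- stats::complete.cases(per_gene[, c("gc3", "gc12")])
  x <- per_gene$gc3[ok]
  y <- per_gene$gc12[ok]
  if (length(x) < 3L) stop("need at least 3 genes for a neutrality fit")
  if (stats::sd(x) == 0) stop("GC3 is constant across genes: slope undefined")
  fit <- stats::lm(y ~ x)
  coefs <- summary(fit)$coefficients
  slope <- unname(coefs["x", "Estimate"])
  p <- unname(coefs["x", "Pr(>|t|)"])
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  # zero-residual fits give a NaN p-value: an exact non-flat line is
  # perfectly significant, an exactly flat one has no slope signal at all
  if (!is.finite(p)) p <- if (slope != 0) 0 else 1
  non_sig <- !(p < alpha)
  structure(
    list(slope = slope, intercept = unname(coefs["(Intercept)", "Estimate"]),
         slope_se = unname(coefs["x", "Std. Error"]),
         r = r, p_value = p, n_genes = length(x), abs_slope = abs(slope),
         selection_pct = if (non_sig) 100 else selection_percent(abs(slope)),
         non_significant = non_sig, alpha = alpha),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "neutrality fit (n = %d): slope %.4f (r = %.3f, p = %.3g)\n",
    x$n_genes, x$slope, x$r, x$p_value))
  cat(sprintf("  selection on codon usage: %.1f%%%s\n", x$selection_pct,
              if (x$non_significant) " [correlation non-significant]" else ""))
  invisible(x)
}

#' Selection percentage from a neutrality-plot slope
#'
#' The absolute slope times 100 measures the share of mutational bias; its
#' complement \code{(1 - abs_slope) * 100} is the percentage of selection on
#' codon usage. Values are negative (and flagged with a warning) when
#' \code{abs_slope > 1}.
#'
#' @param abs_slope Absolute value of the neutrality-plot slope (>= 0).
#' @return Percentage of selective constraint on codon usage.
#' @examples
#' selection_percent(0.31) # 69
#' @export
selection_percent <- function(abs_slope) {
  if (any(abs_slope < 0)) stop("abs_slope must be non-negative")
  out <- (1 - abs_slope) * 100
  if (any(out < 0)) warning("abs_slope > 1: negative selection percentage")
  out
}

#' Expected ENC under mutational GC3 bias alone (Wright's curve)
#'
#' ENCexp(s) = 2 + s + constant / (s^2 + (1 - s)^2) with s the GC3 fraction.
#' With the default constant 29 the curve peaks just above s = 0.5 at about
#' 61 effective codons and falls toward 31 (s = 0) and 32 (s = 1). Genes
#' lying clearly below the curve use fewer codons than their base composition
#' explains, a sign of selection on codon usage.
#'
#' @param gc3 GC3 fraction(s) in [0, 1].
#' @param constant Curve constant (default 29, Wright's value).
#' @return Expected ENC value(s).
#' @export
enc_expected <- function(gc3, constant = 29) {
  if (any(gc3 < 0 | gc3 > 1)) stop("gc3 must lie in [0, 1]")
  2 + gc3 + constant / (gc3^2 + (1 - gc3)^2)
}

#' Per-gene selection calls from the ENC/GC3 plot
#'
#' For each gene, dNCsg = observed ENC minus expected ENC at the gene's GC3;
#' genes with dNCsg < 0 (strictly) lie below the curve and are called under
#' selection for codon usage. Genes with undefined ENC are excluded and
#' counted in the \code{n_excluded} attribute.
#'
#' @param metrics Per-gene table from \code{\link{gene_metrics}} (columns
#'   gene_id, enc, gc3).
#' @param constant Curve constant passed to \code{\link{enc_expected}}.
#' @return \code{data.frame} with gene_id, enc_obs, gc3, enc_exp, dnc_sg and
#'   under_selection; attribute \code{n_excluded} gives the number of genes
#'   dropped for undefined ENC.
#' @export
gene_selection_calls <- function(metrics, constant = 29) {
  stopifnot(is.data.frame(metrics),
            all(c("gene_id", "enc", "gc3") %in% names(metrics)))
  defined <- !is.na(metrics$enc)
  m <- metrics[defined, , drop = FALSE]
  enc_exp <- enc_expected(m$gc3, constant = constant)
  out <- data.frame(gene_id = m$gene_id, enc_obs = m$enc, gc3 = m$gc3,
                    enc_exp = enc_exp, dnc_sg = m$enc - enc_exp,
                    under_selection = (m$enc - enc_exp) < 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!defined)
  out
}

#' Percentage of genes under selection for codon usage (dNC)
#'
#' dNC = 100 * (number of genes with dNCsg < 0) / (number of genes with a
#' defined ENC).
#'
#' @param calls Output of \code{\link{gene_selection_calls}}.
#' @return Percentage in [0, 100].
#' @export
dnc_percent <- function(calls) {
  stopifnot(is.data.frame(calls), "under_selection" %in% names(calls))
  if (nrow(calls) == 0L) stop("no selection calls: dNC undefined")
  100 * sum(calls$under_selection) / nrow(calls)
}

#' Codon-usage profile of the genes under selection
#'
#' Pools codon counts over only the genes called under selection (below the
#' ENC/GC3 curve) and recomputes the genome profile on that subset, enabling
#' comparison of subset GC3/RSCU against genome-wide values.
#'
#' @param genes Gene table the calls were computed from.
#' @param calls Output of \code{\link{gene_selection_calls}} for these genes.
#' @param ... Passed to \code{\link{genome_profile}}.
#' @return A \code{genome_profile} over the selected subset.
#' @export
selected_subset_profile <- function(genes, calls, ...) {
  sel_ids <- calls$gene_id[calls$under_selection]
  subset <- genes[genes$gene_id %in% sel_ids, , drop = FALSE]
  if (nrow(subset) == 0L) {
    stop("no genes under selection: subset profile undefined ",
         "(all genes lie on or above the expected ENC/GC3 curve)")
  }
  genome_profile(subset, ...)
}
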