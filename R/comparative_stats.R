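#' Nonparametric group comparison of a genome-level trait
#'
#' Kruskal-Wallis test across all groups followed by two-sided Wilcoxon
#' rank-sum tests for every unordered group pair with Bonferroni adjustment
#' over the number of pairs. Groups with fewer than \code{min_group_size}
#' members are excluded with a warning (mirroring the exclusion of
#' single-genome families from between-group statistics).
#'
#' @param values Named numeric vector: genome_id -> trait value.
#' @param groups Named character vector: genome_id -> group label.
#' @param trait Trait name carried into the result (for reporting).
#' @param min_group_size Minimum members per usable group (default 2).
#' @return A \code{group_comparison} object: trait, kw_statistic, kw_p,
#'   pairwise (matrix of Bonferroni-adjusted p-values), n_per_group,
#'   n_comparisons.
#' @export
group_compare <- function(values, groups, trait = "trait",
                          min_group_size = 2L) {
  stopifnot(!is.null(names(values)), !is.null(names(groups)))
  shared <- intersect(names(values), names(groups))
  v <- values[shared]
  g <- as.character(groups[shared])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    warning("excluding group(s) with < ", min_group_size, " members: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    v <- v[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2L) {
    stop("need at least 2 groups with >= ", min_group_size, " members")
  }
  kw <- stats::kruskal.test(v, factor(g))
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(v, factor(g), p.adjust.method = "bonferroni")
  )
  structure(
    list(trait = trait, kw_statistic = unname(kw$statistic),
         kw_p = kw$p.value, pairwise = pw$p.value,
         n_per_group = table(g),
         n_comparisons = choose(length(unique(g)), 2L)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison of %s: Kruskal-Wallis chi-sq = %.3f, p = %.3g\n",
              x$trait, x$kw_statistic, x$kw_p))
  cat("pairwise Wilcoxon, Bonferroni-adjusted over", x$n_comparisons,
      "pairs:\n")
  print(signif(x$pairwise, 3))
  invisible(x)
}

#' Spearman rank correlation between two genome-level traits
#'
#' @param x,y Named numeric vectors (genome_id -> value); only genomes
#'   present in both are used, and at least 4 shared genomes are required.
#' @return List with \code{rho}, \code{p} and \code{n}.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(!is.null(names(x)), !is.null(names(y)))
  shared <- intersect(names(x), names(y))
  xv <- x[shared]; yv <- y[shared]
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 4L) stop("need at least 4 shared genomes")
  ct <- suppressWarnings(
    stats::cor.test(xv[ok], yv[ok], method = "spearman")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Normality and homoscedasticity report for grouped traits
#'
#' Shapiro-Wilk normality test on the pooled trait values and Bartlett's
#' test of equal variances across groups. Reporting only: the comparison
#' pipeline proceeds nonparametrically regardless.
#'
#' @param values Named numeric vector (genome_id -> value).
#' @param groups Named character vector (genome_id -> group).
#' @return \code{data.frame} with test, statistic and p_value rows.
#' @export
normality_report <- function(values, groups) {
  shared <- intersect(names(values), names(groups))
  v <- values[shared]
  g <- factor(as.character(groups[shared]))
  sw <- stats::shapiro.test(v)
  bt <- stats::bartlett.test(v, g)
  data.frame(
    test = c("shapiro_wilk", "bartlett"),
    statistic = c(unname(sw$statistic), unname(bt$statistic)),
    p_value = c(sw$p.value, bt$p.value),
    stringsAsFactors = FALSE
  )
}

#' Phylogenetically independent contrasts of a tip trait
#'
#' Felsenstein's contrasts via \code{\link[ape]{pic}}: standardized
#' differences of trait values at the n - 1 internal nodes of a rooted,
#' bifurcating tree, which are mutually independent under Brownian motion.
#' Polytomies are resolved into zero-length bifurcations first; a contrast
#' whose two (variance-extended) sibling branches are both zero-length is
#' degenerate and raises an error naming the node.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths; tip labels
#'   must cover all names of \code{trait}.
#' @param trait Named numeric vector (tip label -> value).
#' @return Numeric vector of n_tips - 1 standardized contrasts (named by
#'   internal node number).
#' @export
pic_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(trait)))
  missing_tips <- setdiff(tree$tip.label, names(trait))
  if (length(missing_tips)) {
    stop("trait values missing for tips: ",
         paste(missing_tips, collapse = ", "))
  }
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # flag degenerate sibling pairs (both child edges of a node zero-length)
  parents <- tree$edge[, 1]
  for (node in unique(parents)) {
    child_edges <- which(parents == node)
    if (length(child_edges) == 2L &&
        all(tree$edge.length[child_edges] == 0)) {
      stop("zero-length sibling branch pair at node ", node,
           ": contrast undefined")
    }
  }
  ape::pic(trait[tree$tip.label], tree)
}

#' Correlation of paired independent contrasts
#'
#' Contrasts have an arbitrary sign, so the correlation is computed through
#' the origin: rho = sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2)), with a
#' two-sided t-test on n - 1 degrees of freedom.
#'
#' @param cx,cy Equal-length contrast vectors from the same tree traversal.
#' @return List with \code{rho}, \code{p} and \code{n} (number of contrasts).
#' @export
correlate_contrasts <- function(cx, cy) {
  if (length(cx) != length(cy)) {
    stop("contrast vectors differ in length (", length(cx), " vs ",
         length(cy), ")")
  }
  n <- length(cx)
  if (n < 2L) stop("need at least 2 contrasts")
  rho <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- n - 1L
  tstat <- rho * sqrt(df) / sqrt(max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(rho = rho, p = p, n = n)
}

#' Hierarchical Euclidean clustering of genome profiles
#'
#' Agglomerative clustering (default complete linkage) on Euclidean
#' distances between per-genome numeric profiles (amino-acid compositions or
#' RSCU vectors). Missing RSCU entries (zero-count families) are imputed
#' with the family-neutral value 1 so vectors stay comparable.
#'
#' @param profiles Named list of equal-length numeric vectors, or a numeric
#'   matrix with one row per genome.
#' @param linkage Agglomeration method for \code{\link[stats]{hclust}}
#'   (default "complete").
#' @param impute_na Value substituted for missing entries (default 1, the
#'   neutral RSCU).
#' @return An \code{hclust} object (merge tree, heights, leaf order).
#' @export
cluster_genomes <- function(profiles, linkage = "complete", impute_na = 1) {
  if (is.list(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1L) {
      stop("profile vectors differ in length")
    }
    profiles <- do.call(rbind, profiles)
  }
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 2L) stop("need at least 2 genomes to cluster")
  profiles[is.na(profiles)] <- impute_na
  stats::hclust(stats::dist(profiles, method = "euclidean"),
                method = linkage)
}

#' Hypergeometric enrichment of annotation terms in a study gene set
#'
#' For every term annotated to at least one study gene, the one-sided
#' hypergeometric upper-tail probability of observing at least the study
#' count given the population count, with Bonferroni correction over the
#' tested terms.
#'
#' @param study_genes Character vector: the study set (e.g. genes under
#'   selection); must be a subset of \code{population_genes}.
#' @param population_genes Character vector: the background gene universe.
#' @param annotations \code{data.frame} with columns \code{gene_id} and
#'   \code{term} (one row per gene-term pair), or a named list gene ->
#'   character vector of terms.
#' @return \code{data.frame} sorted by adjusted p with columns term, k_study,
#'   n_study, k_pop, n_pop, p_raw, p_bonferroni.
#' @export
term_enrichment <- function(study_genes, population_genes, annotations) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  if (length(study_genes) == 0L) stop("empty study set")
  extra <- setdiff(study_genes, population_genes)
  if (length(extra)) {
    stop("study genes missing from population: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- data.frame(
      gene_id = rep(names(annotations), lengths(annotations)),
      term = unlist(annotations, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("gene_id", "term") %in% names(annotations)))
  ann <- unique(annotations[annotations$gene_id %in% population_genes,
                            c("gene_id", "term")])
  n_pop <- length(population_genes)
  n_study <- length(study_genes)
  in_study <- ann$gene_id %in% study_genes
  terms <- unique(ann$term[in_study])
  if (length(terms) == 0L) {
    return(data.frame(term = character(0), k_study = integer(0),
                      n_study = integer(0), k_pop = integer(0),
                      n_pop = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0)))
  }
  rows <- lapply(terms, function(tm) {
    k_pop <- sum(ann$term == tm)
    k_study <- sum(ann$term == tm & in_study)
    p <- stats::phyper(k_study - 1L, k_pop, n_pop - k_pop, n_study,
                       lower.tail = FALSE)
    data.frame(term = tm, k_study = k_study, n_study = n_study,
               k_pop = k_pop, n_pop = n_pop, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out <- out[order(out$p_bonferroni, out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}
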