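test_that("group comparison separates disjoint groups and drops tiny ones", {
  vals <- setNames(c(1:10 / 100, 5 + 1:10 / 100), paste0("g", 1:20))
  grp <- setNames(rep(c("A", "B"), each = 10), paste0("g", 1:20))
  res <- group_compare(vals, grp, trait = "enc")
  expect_lt(res$kw_p, 0.001)
  expect_lt(max(res$pairwise, na.rm = TRUE), 0.001)

  grp2 <- c(grp, g21 = "C")
  vals2 <- c(vals, g21 = 3)
  expect_warning(res2 <- group_compare(vals2, grp2), "excluding")
  expect_false("C" %in% c(rownames(res2$pairwise), colnames(res2$pairwise)))

  expect_error(suppressWarnings(
    group_compare(setNames(1:3, c("a", "b", "c")),
                  setNames(c("A", "A", "B"), c("a", "b", "c")))),
    "at least 2 groups")
})

test_that("identical groups yield no spurious pairwise signal", {
  set.seed(14)
  vals <- setNames(rnorm(20), paste0("g", 1:20))
  grp <- setNames(rep(c("A", "B"), 10), paste0("g", 1:20))
  res <- group_compare(vals, grp)
  expect_gt(min(res$pairwise, na.rm = TRUE), 0.05)
})

test_that("Bonferroni-adjusted p-values never decrease and never exceed 1", {
  set.seed(31)
  vals <- setNames(rnorm(30), paste0("g", 1:30))
  grp <- setNames(rep(c("A", "B", "C"), each = 10), paste0("g", 1:30))
  res <- group_compare(vals, grp)
  raw <- suppressWarnings(stats::pairwise.wilcox.test(
    vals, factor(grp), p.adjust.method = "none"))$p.value
  adj <- res$pairwise
  expect_true(all(adj >= raw - 1e-12, na.rm = TRUE))
  expect_true(all(adj <= 1, na.rm = TRUE))
  expect_equal(adj, pmin(raw * res$n_comparisons, 1), tolerance = 1e-12)
})

test_that("Spearman correlation handles monotone and reversed traits", {
  x <- setNames(c(1, 3, 2, 8, 5, 4), paste0("g", 1:6))
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  # one adjacent swap among 6 ranks: rho = 1 - 6*2/(6*35)
  y <- setNames(c(1, 2, 4, 3, 5, 6), paste0("g", 1:6))
  xr <- setNames(as.numeric(1:6), paste0("g", 1:6))
  expect_equal(spearman_corr(xr, y)$rho, 1 - 12 / 210, tolerance = 1e-10)
  expect_error(spearman_corr(x[1:3], x[1:3]), "at least 4")
})

test_that("normality report returns Shapiro-Wilk and Bartlett results", {
  set.seed(8)
  vals <- setNames(c(rnorm(15), rexp(15, 0.2)), paste0("g", 1:30))
  grp <- setNames(rep(c("A", "B"), each = 15), paste0("g", 1:30))
  rep_ <- normality_report(vals, grp)
  expect_equal(rep_$test, c("shapiro_wilk", "bartlett"))
  expect_true(all(rep_$p_value >= 0 & rep_$p_value <= 1))
})

test_that("independent contrasts match hand evaluation on a cherry", {
  tree <- ape::read.tree(text = "(a:1,b:1);")
  ct <- pic_contrasts(tree, c(a = 3, b = 1))
  expect_equal(unname(ct), 2 / sqrt(2), tolerance = 1e-9)

  # identical tip values -> all contrasts zero
  big <- ape::rtree(12)
  ct0 <- pic_contrasts(big, setNames(rep(2.5, 12), big$tip.label))
  expect_equal(unname(ct0), rep(0, 11))

  expect_error(pic_contrasts(tree, c(a = 1)), "missing")
  zero <- ape::read.tree(text = "(a:0,b:0);")
  expect_error(pic_contrasts(zero, c(a = 1, b = 2)), "zero-length")
})

test_that("contrasts agree with ape on a polytomy-resolved tree", {
  set.seed(12)
  tree <- ape::rtree(10)
  trait <- setNames(rnorm(10), tree$tip.label)
  expect_equal(unname(pic_contrasts(tree, trait)),
               unname(ape::pic(trait, tree)))
})

test_that("star-like trees reduce contrasts to scaled tip differences", {
  tree <- ape::read.tree(text = "((a:1,b:1):1e-9,(c:1,d:1):1e-9);")
  trait <- c(a = 4, b = 1, c = 2, d = 7)
  ct <- pic_contrasts(tree, trait)
  expect_true(any(abs(abs(ct) - abs(4 - 1) / sqrt(2)) < 1e-3))
  expect_true(any(abs(abs(ct) - abs(2 - 7) / sqrt(2)) < 1e-3))
})

test_that("contrast correlation is computed through the origin", {
  cx <- c(1.2, -0.4, 2.2, 0.3, -1.8)
  expect_equal(correlate_contrasts(cx, 2 * cx)$rho, 1)
  # orthogonal by construction
  cy <- c(1, 1, 0, 0, 0)
  cz <- c(0, 0, 2, -1, 3)
  expect_equal(correlate_contrasts(cy, cz)$rho, 0)
  expect_error(correlate_contrasts(cx, cx[1:3]), "length")
})

test_that("contrast correlations are calibrated under the null", {
  set.seed(77)
  n_sig <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    sim <- simulate_tree_and_traits(tree_sim_spec(24, 0, seed = 1000 + i))
    cx <- pic_contrasts(sim$tree, setNames(sim$traits$trait1,
                                           sim$traits$tip))
    cy <- pic_contrasts(sim$tree, setNames(sim$traits$trait2,
                                           sim$traits$tip))
    if (correlate_contrasts(cx, cy)$p < 0.05) n_sig <- n_sig + 1
  }
  # ~5% type-I error; allow binomial slack for 60 replicates
  expect_lte(n_sig, 9)
})

test_that("Euclidean clustering orders merges by profile distance", {
  profs <- list(a = c(0, 0), b = c(0, 0), c = c(10, 0))
  hc <- cluster_genomes(profs)
  expect_equal(hc$height[1], 0)          # identical profiles merge first
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))

  profs2 <- list(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  hc2 <- cluster_genomes(profs2)
  expect_equal(hc2$height, c(1, 10))     # complete linkage on the line

  # input order leaves merge heights unchanged
  hc3 <- cluster_genomes(profs2[c(3, 1, 2)])
  expect_equal(sort(hc2$height), sort(hc3$height))

  expect_error(cluster_genomes(list(a = 1:2, b = 1:3)), "length")
  # missing RSCU entries imputed at the neutral value 1
  hc4 <- cluster_genomes(list(a = c(1, NA), b = c(1, 1)))
  expect_equal(hc4$height, 0)
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  pop <- paste0("g", 1:100)
  ann <- data.frame(gene_id = pop[1:10], term = "T1",
                    stringsAsFactors = FALSE)
  # study of 10 genes containing all 10 annotated ones: p = 1/C(100,10)
  res <- term_enrichment(pop[1:10], pop, ann)
  expect_equal(res$p_raw, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(res$k_study, 10L)

  # study = population -> p = 1 for every term
  res2 <- term_enrichment(pop, pop, ann)
  expect_equal(res2$p_raw, 1)

  # terms absent from the study set are not tested
  ann2 <- rbind(ann, data.frame(gene_id = pop[90], term = "T2"))
  res3 <- term_enrichment(pop[1:10], pop, ann2)
  expect_false("T2" %in% res3$term)

  # Bonferroni over tested terms, capped at 1
  ann3 <- rbind(ann, data.frame(gene_id = pop[1:5], term = "T3"))
  res4 <- term_enrichment(pop[1:10], pop, ann3)
  expect_equal(res4$p_bonferroni, pmin(1, res4$p_raw * 2))

  expect_error(term_enrichment(character(0), pop, ann), "empty study")
  expect_error(term_enrichment("nope", pop, ann), "missing from population")
})
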