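# Synthetic CDS generator. Genomes are simulated gene by gene under an
# explicit mutation-selection dichotomy: third-codon positions follow a
# gene-level GC3 target drawn around the genome's mutational GC3, GC12
# follows GC3 through a linear neutrality relation with known slope, and a
# configurable fraction of genes additionally concentrates synonymous usage
# on preferred codons (selection), lowering their ENC.

# default amino-acid composition (percent): the near-universal ranking with
# Ala/Leu/Ser high and Cys/His/Met/Trp low, as seen across fungal genomes
DEFAULT_AA_FREQS <- c(
  A = 8.8, C = 1.3, D = 5.5, E = 6.2, F = 4.0, G = 6.6, H = 2.3, I = 5.3,
  K = 5.2, L = 9.0, M = 2.2, N = 4.2, P = 5.4, Q = 4.0, R = 5.6, S = 8.0,
  T = 5.8, V = 6.5, W = 1.4, Y = 3.0
)

# per-amino-acid codon sets split by third-position base class
FAM_GC_ENDING <- lapply(AA_FAMILIES, function(cods) cods[CODON_GC3[cods]])
FAM_AT_ENDING <- lapply(AA_FAMILIES, function(cods) cods[!CODON_GC3[cods]])

default_preferred_codons <- function() {
  vapply(names(AA_DEGENERACY)[AA_DEGENERACY > 1L], function(aa) {
    gc_end <- FAM_GC_ENDING[[aa]]
    c_end <- gc_end[substr(gc_end, 3L, 3L) == "C"]
    if (length(c_end)) c_end[1] else gc_end[1]
  }, character(1))
}

#' Specification of one simulated genome
#'
#' Bundles and validates the generating parameters of a synthetic genome:
#' mutational GC3 target, between-gene GC3 spread, the linear GC12~GC3
#' neutrality relation (known ground-truth slope), and codon-level selection
#' (fraction of genes, strength multiplier on preferred codons, by default
#' the C-ending — else G-ending — codon of each synonymous family).
#'
#' @param genome_id Genome identifier.
#' @param group Group label for between-group comparisons.
#' @param n_genes Number of genes.
#' @param gene_length_codons Two-element range of gene lengths in sense
#'   codons (start and stop codons are added on top).
#' @param mut_gc3 Genome-wide third-position GC fraction under pure mutation.
#' @param gc3_sd Between-gene standard deviation of the GC3 target.
#' @param neutrality_slope Generating slope of the GC12~GC3 relation.
#' @param neutrality_intercept Intercept of that relation; default places
#'   GC12 at 0.46 when GC3 equals \code{mut_gc3}.
#' @param gc12_noise_sd Gaussian noise on the per-gene GC12 target.
#' @param sel_fraction Fraction of genes under codon-level selection.
#' @param sel_strength Multiplier (>= 1) on preferred-codon probabilities in
#'   selected genes; 1 disables selection.
#' @param preferred_codons Named character vector (amino acid -> codon);
#'   default GC-ending codons.
#' @param aa_freqs Base amino-acid composition (named over the 20 one-letter
#'   codes; normalized internally).
#' @param allocation How synonymous codons of neutral genes realize their
#'   target frequencies: \code{"balanced"} (default) allocates within-gene
#'   counts at the target shares up to rounding, so neutral genes track the
#'   expected ENC/GC3 curve tightly; \code{"multinomial"} draws each codon
#'   independently, adding within-gene sampling noise that scatters genes
#'   symmetrically about the curve.
#' @param seed Integer seed; the same spec always yields the same genome.
#' @return A \code{genome_sim_spec} object (validated list).
#' @export
genome_sim_spec <- function(genome_id, group = "G1", n_genes = 500,
                            gene_length_codons = c(200, 600),
                            mut_gc3 = 0.65, gc3_sd = 0.10,
                            neutrality_slope = 0.15,
                            neutrality_intercept = NULL,
                            gc12_noise_sd = 0.02,
                            sel_fraction = 0, sel_strength = 1,
                            preferred_codons = NULL,
                            aa_freqs = NULL,
                            allocation = c("balanced", "multinomial"),
                            seed = 1L) {
  allocation <- match.arg(allocation)
  stopifnot(n_genes >= 1, length(gene_length_codons) == 2L,
            gene_length_codons[1] >= 34, diff(gene_length_codons) >= 0,
            mut_gc3 >= 0, mut_gc3 <= 1, gc3_sd >= 0,
            sel_fraction >= 0, sel_fraction <= 1, sel_strength >= 1,
            gc12_noise_sd >= 0)
  if (is.null(preferred_codons)) preferred_codons <- default_preferred_codons()
  if (is.null(aa_freqs)) aa_freqs <- DEFAULT_AA_FREQS
  stopifnot(setequal(names(aa_freqs), AA_LETTERS), all(aa_freqs > 0))
  aa_freqs <- aa_freqs[AA_LETTERS] / sum(aa_freqs[AA_LETTERS])
  pref_gc <- CODON_GC3[preferred_codons]
  if (sel_strength > 1 && mut_gc3 == 0 && all(pref_gc)) {
    stop("impossible constraints: mut_gc3 = 0 forbids the GC-ending ",
         "preferred codons that sel_strength > 1 demands")
  }
  if (is.null(neutrality_intercept)) {
    neutrality_intercept <- 0.46 - neutrality_slope * mut_gc3
  }
  structure(
    list(genome_id = genome_id, group = group, n_genes = as.integer(n_genes),
         gene_length_codons = as.integer(gene_length_codons),
         mut_gc3 = mut_gc3, gc3_sd = gc3_sd,
         neutrality_slope = neutrality_slope,
         neutrality_intercept = neutrality_intercept,
         gc12_noise_sd = gc12_noise_sd,
         sel_fraction = sel_fraction, sel_strength = sel_strength,
         preferred_codons = preferred_codons, aa_freqs = aa_freqs,
         allocation = allocation, seed = as.integer(seed)),
    class = "genome_sim_spec"
  )
}

# allocate n slots over candidate codons at (near-)equal expected shares:
# floor of the expected count each, remainder assigned at random, order
# shuffled; keeps realized within-gene usage at its target up to rounding
balanced_fill <- function(cands, n, prob = NULL) {
  k <- length(cands)
  if (k == 1L) return(rep(cands, n))
  if (is.null(prob)) prob <- rep(1 / k, k)
  expect <- n * prob / sum(prob)
  counts <- floor(expect)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- sample(k, rem, prob = pmax(expect - counts, 1e-9))
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(cands, counts))
}

# exponential tilt of the amino-acid composition so that the expected GC
# fraction of codon positions 1-2 matches the gene's GC12 target
tilt_aa_weights <- function(target, base) {
  m <- AA_GC12[names(base)]
  ev <- function(t) {
    w <- base * exp(t * m)
    sum(w * m) / sum(w)
  }
  lo <- -60; hi <- 60
  target <- min(max(target, ev(lo) + 1e-7), ev(hi) - 1e-7)
  root <- stats::uniroot(function(t) ev(t) - target, c(lo, hi),
                         tol = 1e-9)$root
  w <- base * exp(root * m)
  w / sum(w)
}

# codon choice for neutral genes: each slot has a fixed third-position base
# class (z TRUE = G/C-ending); codons are drawn uniformly within the class,
# either by minimal-variance balanced allocation or multinomially
sample_codons_zplan <- function(aa, z, balanced = TRUE) {
  codons <- character(length(aa))
  key <- paste0(aa, as.integer(z))
  for (k in unique(key)) {
    idx <- which(key == k)
    this_aa <- aa[idx[1]]
    cands <- if (z[idx[1]]) FAM_GC_ENDING[[this_aa]] else
      FAM_AT_ENDING[[this_aa]]
    if (length(cands) == 0L) cands <- AA_FAMILIES[[this_aa]]  # Met/Trp force G
    codons[idx] <- if (length(cands) == 1L) rep(cands, length(idx))
      else if (balanced) balanced_fill(cands, length(idx))
      else sample(cands, length(idx), replace = TRUE)
  }
  codons
}

# codon choice for selected genes: third-position base probabilities follow
# the gene GC3 target, with preferred codons upweighted by sel_strength
sample_codons_selected <- function(aa, t3, strength, preferred) {
  codons <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    fam <- AA_FAMILIES[[a]]
    n_gc <- sum(CODON_GC3[fam]); n_at <- length(fam) - n_gc
    w <- ifelse(CODON_GC3[fam],
                if (n_gc) t3 / n_gc else 0,
                if (n_at) (1 - t3) / n_at else 0)
    if (all(w == 0)) w <- rep(1, length(fam))
    if (a %in% names(preferred)) {
      w[fam == preferred[[a]]] <- w[fam == preferred[[a]]] * strength
    }
    codons[idx] <- if (length(fam) == 1L) fam else
      sample(fam, length(idx), replace = TRUE, prob = w)
  }
  codons
}

#' Simulate one genome's CDS set
#'
#' Per gene: a GC3 target is drawn around the genome's mutational GC3 and a
#' GC12 target follows it through the neutrality relation; amino acids are
#' sampled from a composition tilted to meet the GC12 target, and
#' third-position G/C slots are then allocated (Met/Trp slots forced to G)
#' so realized GC3 matches its target exactly under balanced allocation —
#' OLS slope recovery is therefore free of errors-in-variables attenuation.
#' Selected genes instead draw codons with preferred-codon probabilities
#' multiplied by \code{sel_strength}. Every
#' gene gets an ATG start and a stop codon and contains no internal stops,
#' so the whole output passes \code{\link{qc_filter}} by construction.
#'
#' @param spec A \code{\link{genome_sim_spec}}.
#' @return Gene table (as \code{\link{read_cds_fasta}}) with a
#'   \code{"truth"} attribute: per-gene data.frame of generating values
#'   (selected flag, GC3/GC12 targets, length).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  set.seed(spec$seed)
  base <- spec$aa_freqs
  lens <- spec$gene_length_codons
  n <- spec$n_genes
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    L <- if (lens[1] == lens[2]) lens[1] else sample(lens[1]:lens[2], 1L)
    t3 <- min(max(stats::rnorm(1, spec$mut_gc3, spec$gc3_sd), 0.03), 0.97)
    selected <- stats::runif(1) < spec$sel_fraction && spec$sel_strength > 1
    g12 <- spec$neutrality_intercept + spec$neutrality_slope * t3 +
      stats::rnorm(1, 0, spec$gc12_noise_sd)
    w_aa <- tilt_aa_weights(g12, base)
    aa <- sample(names(w_aa), L, replace = TRUE, prob = w_aa)
    if (selected) {
      codons <- sample_codons_selected(aa, t3, spec$sel_strength,
                                       spec$preferred_codons)
    } else {
      # third-position plan: Met/Trp slots force G; the remaining GC-ending
      # slots are placed so the gene's realized GC3 equals its target
      # exactly (balanced) or in expectation (multinomial)
      forced <- aa %in% c("M", "W")
      n_forced <- sum(forced)
      z <- forced
      free <- which(!forced)
      if (spec$allocation == "balanced") {
        extra <- min(max(round(t3 * L) - n_forced, 0L), length(free))
        if (extra > 0L) z[sample(free, extra)] <- TRUE
      } else {
        p_free <- min(max((t3 * L - n_forced) / length(free), 0), 1)
        z[free] <- stats::rbinom(length(free), 1L, p_free) == 1L
      }
      codons <- sample_codons_zplan(aa, z,
                                    balanced = spec$allocation == "balanced")
    }
    stop_codon <- sample(STOP_CODONS, 1L)
    seqs[i] <- paste0("ATG", paste(codons, collapse = ""), stop_codon)
    truth[[i]] <- data.frame(
      gene_id = sprintf("%s_g%04d", spec$genome_id, i),
      genome_id = spec$genome_id, selected = selected,
      target_gc3 = t3, target_gc12 = g12, n_codons = L + 1L,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  genes <- data.frame(
    gene_id = truth$gene_id, genome_id = spec$genome_id,
    sequence = seqs, source = "cds_fasta", stringsAsFactors = FALSE
  )
  attr(genes, "truth") <- truth
  genes
}

#' Simulate a cohort of genomes and (optionally) write its files
#'
#' @param specs List of \code{\link{genome_sim_spec}} objects with unique
#'   genome ids.
#' @param out_dir Optional directory; when given, one CDS FASTA per genome,
#'   a \code{groups.tsv} (genome_id, group), a per-gene \code{truth.tsv}
#'   (selected flag and generating targets) and a \code{params.tsv}
#'   (per-genome generating parameters) are written there.
#' @param base_seed Optional integer; when given, overrides each spec's seed
#'   deterministically (hierarchical seeding, one integer drives the cohort).
#' @return List with \code{genes} (combined gene table), \code{truth},
#'   \code{groups} and, when written, \code{paths}.
#' @export
simulate_cohort <- function(specs, out_dir = NULL, base_seed = NULL) {
  if (length(specs) == 0L) stop("empty cohort specification")
  ids <- vapply(specs, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  }
  if (!is.null(base_seed)) {
    for (i in seq_along(specs)) {
      specs[[i]]$seed <- as.integer(
        ((base_seed %% 1000003) * 1009 + i) %% .Machine$integer.max)
    }
  }
  sims <- lapply(specs, simulate_genome)
  genes <- do.call(rbind, sims)
  rownames(genes) <- NULL
  truth <- do.call(rbind, lapply(sims, attr, "truth"))
  rownames(truth) <- NULL
  groups <- data.frame(
    genome_id = ids,
    group = vapply(specs, `[[`, character(1), "group"),
    stringsAsFactors = FALSE
  )
  out <- list(genes = genes, truth = truth, groups = groups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fasta_paths <- vapply(seq_along(specs), function(i) {
      p <- file.path(out_dir, paste0(ids[i], ".fasta"))
      write_cds_fasta(sims[[i]], p)
      p
    }, character(1))
    params <- do.call(rbind, lapply(specs, function(s) {
      data.frame(genome_id = s$genome_id, group = s$group,
                 n_genes = s$n_genes, mut_gc3 = s$mut_gc3,
                 gc3_sd = s$gc3_sd, neutrality_slope = s$neutrality_slope,
                 sel_fraction = s$sel_fraction, sel_strength = s$sel_strength,
                 seed = s$seed, stringsAsFactors = FALSE)
    }))
    tsv <- function(d, name) {
      p <- file.path(out_dir, name)
      utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    out$paths <- list(
      fasta = stats::setNames(fasta_paths, ids),
      groups = tsv(groups, "groups.tsv"),
      truth = tsv(truth, "truth.tsv"),
      params = tsv(params, "params.tsv")
    )
  }
  out
}

#' Specification of a simulated phylogeny with correlated Brownian traits
#'
#' @param n_tips Number of tips (>= 2).
#' @param bm_correlation Target correlation of the two Brownian traits,
#'   strictly inside (-1, 1).
#' @param seed Integer seed.
#' @return A \code{tree_sim_spec} object.
#' @export
tree_sim_spec <- function(n_tips, bm_correlation = 0, seed = 1L) {
  stopifnot(n_tips >= 2)
  if (abs(bm_correlation) >= 1) {
    stop("bm_correlation must lie strictly inside (-1, 1)")
  }
  structure(list(n_tips = as.integer(n_tips),
                 bm_correlation = bm_correlation, seed = as.integer(seed)),
            class = "tree_sim_spec")
}

#' Simulate a pure-birth tree and two correlated Brownian traits
#'
#' A Yule (pure-birth) tree is simulated and two traits are evolved along
#' its branches by correlated Brownian motion: each branch of length b adds
#' a bivariate Gaussian increment with covariance b * Sigma, where Sigma has
#' unit variances and off-diagonal \code{bm_correlation}.
#'
#' @param spec A \code{\link{tree_sim_spec}}.
#' @return List with \code{tree} (\code{phylo}), \code{newick} (text) and
#'   \code{traits} (data.frame: tip, trait1, trait2).
#' @export
simulate_tree_and_traits <- function(spec) {
  stopifnot(inherits(spec, "tree_sim_spec"))
  set.seed(spec$seed)
  tree <- ape::rphylo(spec$n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("g%03d", seq_len(spec$n_tips))
  rho <- spec$bm_correlation
  U <- chol(matrix(c(1, rho, rho, 1), 2L))
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  n_nodes <- spec$n_tips + tr$Nnode
  X <- matrix(0, n_nodes, 2L)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    inc <- sqrt(tr$edge.length[e]) * (stats::rnorm(2L) %*% U)
    X[child, ] <- X[parent, ] + inc
  }
  traits <- data.frame(tip = tr$tip.label,
                       trait1 = X[seq_len(spec$n_tips), 1L],
                       trait2 = X[seq_len(spec$n_tips), 2L],
                       stringsAsFactors = FALSE)
  list(tree = tree, newick = ape::write.tree(tree), traits = traits)
}
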