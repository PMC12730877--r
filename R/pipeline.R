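#' Pipeline configuration
#'
#' Collects all inputs and tunable parameters of a full codon-usage-bias
#' run. \code{cds_files} is a named character vector (genome_id -> CDS FASTA
#' path); groups, tree and annotation inputs are optional and the stages
#' that need them are skipped with a warning when absent.
#'
#' @param cds_files Named character vector of CDS FASTA paths.
#' @param out_dir Output directory for the TSV/plot bundle.
#' @param groups_file Optional TSV with columns genome_id, group.
#' @param tree_file Optional Newick tree whose tips match the genome ids.
#' @param annotations_file Optional TSV with columns gene_id, term.
#' @param min_len_bp Minimum CDS length for quality filtering (default 100).
#' @param enc_curve_constant Constant of the expected ENC curve (default 29).
#' @param neutrality_alpha Significance threshold for neutrality-plot
#'   correlations (default 0.01).
#' @param rscu_over,rscu_under RSCU over-/underrepresentation thresholds
#'   (defaults 1.6, 0.6).
#' @param strong_bias_enc ENC at or below which a gene is flagged as
#'   strongly biased (default 35).
#' @param linkage Clustering linkage method (default "complete").
#' @param make_plots Write neutrality and ENC/GC3 plots per genome (PDF).
#' @param seed Seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return A validated \code{run_config} object.
#' @export
run_config <- function(cds_files, out_dir, groups_file = NULL,
                       tree_file = NULL, annotations_file = NULL,
                       min_len_bp = 100, enc_curve_constant = 29,
                       neutrality_alpha = 0.01,
                       rscu_over = 1.6, rscu_under = 0.6,
                       strong_bias_enc = 35, linkage = "complete",
                       make_plots = FALSE, seed = 1L) {
  stopifnot(length(cds_files) >= 1L, !is.null(names(cds_files)),
            min_len_bp > 0, enc_curve_constant > 0, neutrality_alpha > 0,
            rscu_over > rscu_under, rscu_under > 0, strong_bias_enc > 0)
  missing_files <- cds_files[!file.exists(cds_files)]
  if (length(missing_files)) {
    stop("CDS files not found: ", paste(missing_files, collapse = ", "))
  }
  structure(
    list(cds_files = cds_files, out_dir = out_dir,
         groups_file = groups_file, tree_file = tree_file,
         annotations_file = annotations_file, min_len_bp = min_len_bp,
         enc_curve_constant = enc_curve_constant,
         neutrality_alpha = neutrality_alpha, rscu_over = rscu_over,
         rscu_under = rscu_under, strong_bias_enc = strong_bias_enc,
         linkage = linkage, make_plots = make_plots, seed = as.integer(seed)),
    class = "run_config"
  )
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes quality filtering, per-gene metrics, genome profiles,
#' neutrality and ENC/GC3 selection inference, selected-subset profiles,
#' and — when the corresponding inputs are present — group comparisons,
#' profile clustering, phylogenetically corrected trait correlations and
#' term enrichment. All results are written as TSV files under
#' \code{config$out_dir}, plus a run log; re-running with the same inputs
#' reproduces the TSVs byte for byte.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with every computed table and object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("cubtools", as.character(utils::packageVersion("cubtools")),
       "| R", paste(R.version$major, R.version$minor, sep = "."))
  for (p in c("min_len_bp", "enc_curve_constant", "neutrality_alpha",
              "rscu_over", "rscu_under", "strong_bias_enc", "linkage",
              "seed")) {
    logf("config:", p, "=", config[[p]])
  }

  groups <- NULL
  if (!is.null(config$groups_file) && file.exists(config$groups_file)) {
    gtab <- utils::read.table(config$groups_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    groups <- stats::setNames(gtab$group, gtab$genome_id)
  } else if (!is.null(config$groups_file)) {
    warning("groups file not found; comparative stage will be skipped")
  }

  genomes <- names(config$cds_files)
  qc_reports <- list(); metrics_all <- list(); profiles <- list()
  neutrality_rows <- list(); calls_all <- list(); subset_rows <- list()
  genes_by_genome <- list()
  for (g in genomes) {
    genes <- read_cds_fasta(config$cds_files[[g]], genome_id = g)
    qc <- qc_filter(genes, min_len_bp = config$min_len_bp)
    logf("genome", g, ":", nrow(genes), "input genes,",
         nrow(qc$passed), "passed QC")
    if (nrow(qc$passed) == 0L) {
      stop("qc stage: no genes passed filtering for genome ", g)
    }
    qc_reports[[g]] <- qc$report
    genes_by_genome[[g]] <- qc$passed
    metrics <- gene_metrics(qc$passed)
    metrics$strong_bias <- !is.na(metrics$enc) &
      metrics$enc <= config$strong_bias_enc
    metrics_all[[g]] <- metrics
    grp <- if (!is.null(groups) && g %in% names(groups)) groups[[g]]
           else NA_character_
    prof <- genome_profile(qc$passed, genome_id = g, group = grp,
                           over = config$rscu_over,
                           under = config$rscu_under)
    nf <- neutrality_fit(metrics, alpha = config$neutrality_alpha)
    calls <- gene_selection_calls(metrics,
                                  constant = config$enc_curve_constant)
    calls$genome_id <- g
    dnc <- dnc_percent(calls)
    profiles[[g]] <- prof
    calls_all[[g]] <- calls
    neutrality_rows[[g]] <- data.frame(
      genome_id = g, group = grp, n_genes = nf$n_genes,
      slope = nf$slope, intercept = nf$intercept, r = nf$r,
      p_value = nf$p_value, abs_slope = nf$abs_slope,
      selection_pct = nf$selection_pct,
      non_significant = nf$non_significant,
      gc3_genomewide = prof$gc$gc3, enc_genomewide = prof$enc,
      dnc_pct = dnc, stringsAsFactors = FALSE
    )
    if (any(calls$under_selection)) {
      sp <- selected_subset_profile(qc$passed, calls, genome_id = g,
                                    group = grp)
      subset_rows[[g]] <- data.frame(
        genome_id = g, n_selected = sp$n_genes,
        gc3_selected = sp$gc$gc3, enc_selected = sp$enc,
        gc3_genomewide = prof$gc$gc3, stringsAsFactors = FALSE
      )
    }
  }

  summary_tab <- do.call(rbind, neutrality_rows)
  rownames(summary_tab) <- NULL
  aa_tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id, t(p$aa), stringsAsFactors = FALSE)
  }))
  rscu_tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id, t(p$rscu$values),
               stringsAsFactors = FALSE)
  }))
  metrics_tab <- do.call(rbind, metrics_all)
  rownames(metrics_tab) <- NULL
  calls_tab <- do.call(rbind, calls_all)
  rownames(calls_tab) <- NULL

  results <- list(
    config = config,
    qc_report = do.call(rbind, qc_reports),
    gene_metrics = metrics_tab,
    genome_summary = summary_tab,
    aa_composition = aa_tab,
    rscu = rscu_tab,
    selection_calls = calls_tab,
    selected_subsets = if (length(subset_rows))
      do.call(rbind, subset_rows) else NULL,
    profiles = profiles,
    genes = genes_by_genome
  )
  rownames(results$qc_report) <- NULL
  if (!is.null(results$selected_subsets)) {
    rownames(results$selected_subsets) <- NULL
  }

  write_qc_report(results$qc_report, file.path(config$out_dir,
                                               "qc_report.tsv"))
  write_tsv(metrics_tab, file.path(config$out_dir, "gene_metrics.tsv"))
  write_tsv(summary_tab, file.path(config$out_dir, "genome_summary.tsv"))
  write_tsv(aa_tab, file.path(config$out_dir, "aa_composition.tsv"))
  write_tsv(rscu_tab, file.path(config$out_dir, "rscu.tsv"))
  write_tsv(calls_tab, file.path(config$out_dir, "selection_calls.tsv"))
  if (!is.null(results$selected_subsets)) {
    write_tsv(results$selected_subsets,
              file.path(config$out_dir, "selected_subsets.tsv"))
  }

  if (!is.null(groups) && length(unique(groups[genomes])) >= 2L) {
    comp_rows <- list()
    for (trait in c("enc_genomewide", "gc3_genomewide", "dnc_pct",
                    "abs_slope")) {
      vals <- stats::setNames(summary_tab[[trait]], summary_tab$genome_id)
      gc_res <- tryCatch(
        group_compare(vals, groups, trait = trait),
        error = function(e) {
          logf("compare stage skipped for", trait, ":", conditionMessage(e))
          NULL
        })
      if (is.null(gc_res)) next
      pw <- gc_res$pairwise
      for (i in seq_len(nrow(pw))) for (j in seq_len(ncol(pw))) {
        if (!is.na(pw[i, j])) {
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            trait = trait, group_a = rownames(pw)[i],
            group_b = colnames(pw)[j], kw_p = gc_res$kw_p,
            p_bonferroni = pw[i, j], stringsAsFactors = FALSE)
        }
      }
    }
    if (length(comp_rows)) {
      results$comparisons <- do.call(rbind, comp_rows)
      write_tsv(results$comparisons,
                file.path(config$out_dir, "group_comparisons.tsv"))
    }
    if (length(profiles) >= 2L) {
      aa_mat <- as.matrix(aa_tab[, -1, drop = FALSE])
      rownames(aa_mat) <- aa_tab$genome_id
      rscu_mat <- as.matrix(rscu_tab[, -1, drop = FALSE])
      rownames(rscu_mat) <- rscu_tab$genome_id
      results$aa_clustering <- cluster_genomes(aa_mat,
                                               linkage = config$linkage)
      results$rscu_clustering <- cluster_genomes(rscu_mat,
                                                 linkage = config$linkage)
      write_tsv(linkage_table(results$aa_clustering),
                file.path(config$out_dir, "aa_linkage.tsv"))
      write_tsv(linkage_table(results$rscu_clustering),
                file.path(config$out_dir, "rscu_linkage.tsv"))
    }
  } else if (!is.null(config$groups_file)) {
    logf("comparative stage skipped: no usable group information")
  }

  if (!is.null(config$tree_file) && file.exists(config$tree_file)) {
    tree <- ape::read.tree(config$tree_file)
    shared <- intersect(tree$tip.label, summary_tab$genome_id)
    if (length(shared) >= 4L) {
      tree <- ape::keep.tip(tree, shared)
      corr_rows <- list()
      traits <- c("enc_genomewide", "gc3_genomewide", "dnc_pct", "abs_slope")
      for (i in seq_along(traits)) for (j in seq_along(traits)) {
        if (j <= i) next
        x <- stats::setNames(summary_tab[[traits[i]]],
                             summary_tab$genome_id)[shared]
        y <- stats::setNames(summary_tab[[traits[j]]],
                             summary_tab$genome_id)[shared]
        raw <- spearman_corr(x, y)
        pic_res <- tryCatch({
          cc <- correlate_contrasts(pic_contrasts(tree, x),
                                    pic_contrasts(tree, y))
          c(rho = cc$rho, p = cc$p)
        }, error = function(e) c(rho = NA_real_, p = NA_real_))
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          trait_x = traits[i], trait_y = traits[j],
          spearman_rho = raw$rho, spearman_p = raw$p,
          pic_rho = unname(pic_res["rho"]), pic_p = unname(pic_res["p"]),
          stringsAsFactors = FALSE)
      }
      results$trait_correlations <- do.call(rbind, corr_rows)
      write_tsv(results$trait_correlations,
                file.path(config$out_dir, "trait_correlations.tsv"))
    } else {
      logf("contrast stage skipped: fewer than 4 genomes on the tree")
    }
  }

  if (!is.null(config$annotations_file) &&
      file.exists(config$annotations_file)) {
    ann <- utils::read.table(config$annotations_file, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    enr_rows <- list()
    for (g in genomes) {
      calls <- calls_all[[g]]
      study <- calls$gene_id[calls$under_selection]
      if (length(study) == 0L) next
      enr <- term_enrichment(study, calls$gene_id, ann)
      if (nrow(enr)) {
        enr$genome_id <- g
        enr_rows[[g]] <- enr
      }
    }
    if (length(enr_rows)) {
      results$enrichment <- do.call(rbind, enr_rows)
      rownames(results$enrichment) <- NULL
      write_tsv(results$enrichment,
                file.path(config$out_dir, "enrichment.tsv"))
    }
  }

  if (config$make_plots) {
    pdf_path <- file.path(config$out_dir, "plots.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 5)
    for (g in genomes) {
      plot_neutrality(metrics_all[[g]], main = paste("Neutrality plot:", g))
      plot_enc_gc3(metrics_all[[g]],
                   constant = config$enc_curve_constant,
                   main = paste("ENC/GC3 plot:", g))
    }
    grDevices::dev.off()
    logf("plots written to", pdf_path)
  }
  logf("pipeline complete:", length(genomes), "genomes")
  invisible(results)
}

# flat merge-table view of an hclust object
linkage_table <- function(hc) {
  data.frame(step = seq_len(nrow(hc$merge)),
             member_a = hc$merge[, 1], member_b = hc$merge[, 2],
             height = hc$height, stringsAsFactors = FALSE)
}

#' Neutrality plot (per-gene GC12 against GC3) with OLS line
#'
#' @param metrics Per-gene table from \code{\link{gene_metrics}}.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @return Invisibly, the \code{\link{neutrality_fit}}.
#' @export
plot_neutrality <- function(metrics, ...) {
  nf <- neutrality_fit(metrics)
  graphics::plot(metrics$gc3, metrics$gc12, pch = 16, cex = 0.4,
                 col = "grey40", xlab = "GC3", ylab = "GC12", ...)
  graphics::abline(nf$intercept, nf$slope, col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "slope = %.3f, r = %.2f\nselection = %.1f%%",
    nf$slope, nf$r, nf$selection_pct))
  invisible(nf)
}

#' ENC/GC3 plot with the expected-ENC curve
#'
#' @param metrics Per-gene table from \code{\link{gene_metrics}}.
#' @param constant Curve constant (see \code{\link{enc_expected}}).
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @return Invisibly, the per-gene selection calls.
#' @export
plot_enc_gc3 <- function(metrics, constant = 29, ...) {
  calls <- gene_selection_calls(metrics, constant = constant)
  graphics::plot(calls$gc3, calls$enc_obs, pch = 16, cex = 0.4,
                 col = ifelse(calls$under_selection, "firebrick", "grey40"),
                 xlab = "GC3", ylab = "ENC", ylim = c(20, 62), ...)
  s <- seq(0, 1, length.out = 200)
  graphics::lines(s, pmin(enc_expected(s, constant), 61), lwd = 2,
                  col = "steelblue")
  invisible(calls)
}
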