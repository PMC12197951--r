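#' Default analysis thresholds
#'
#' The pipeline's decision thresholds: DMP adjusted-p 0.05, DEG adjusted-p
#' 0.01 with |log2FC| >= 2, and the correlation rule |r| >= 0.7 at
#' adjusted p <= 0.05. These thresholds are the method's parameters;
#' override them explicitly if you must.
#'
#' @param dmp_alpha,deg_alpha,lfc_min,r_min,corr_alpha Numeric thresholds.
#' @return A named list.
#' @export
default_thresholds <- function(dmp_alpha = 0.05, deg_alpha = 0.01,
                               lfc_min = 2, r_min = 0.7,
                               corr_alpha = 0.05) {
  stopifnot(dmp_alpha > 0, dmp_alpha <= 1, deg_alpha > 0, deg_alpha <= 1,
            lfc_min >= 0, r_min >= 0, r_min <= 1, corr_alpha > 0,
            corr_alpha <= 1)
  list(dmp_alpha = dmp_alpha, deg_alpha = deg_alpha, lfc_min = lfc_min,
       r_min = r_min, corr_alpha = corr_alpha)
}

#' Read a cohort bundle from fixture files
#'
#' Loads the files written by [write_fixture()] (truth tables optional)
#' into the in-memory bundle [run_pipeline()] consumes.
#'
#' @param dir Directory holding `m_values.tsv`, `detection_p.tsv`,
#'   `counts.tsv`, `manifest.csv`, `samples.tsv`.
#' @return A list of class `methx_cohort`.
#' @export
read_cohort <- function(dir) {
  out <- list(
    manifest = read_manifest(file.path(dir, "manifest.csv")),
    m = read_omics_matrix(file.path(dir, "m_values.tsv"), "methylation"),
    detection_p = read_omics_matrix(file.path(dir, "detection_p.tsv"),
                                    "detection_p"),
    counts = read_omics_matrix(file.path(dir, "counts.tsv"), "counts"),
    samples = read_sample_table(file.path(dir, "samples.tsv")))
  tp <- file.path(dir, "truth_probes.tsv")
  tg <- file.path(dir, "truth_genes.tsv")
  if (file.exists(tp) && file.exists(tg)) {
    out$truth <- list(
      probes = readr::read_tsv(tp, show_col_types = FALSE),
      genes = readr::read_tsv(tg, show_col_types = FALSE))
  }
  structure(out, class = "methx_cohort")
}

#' Run the full integrative analysis
#'
#' Orchestrates the complete pipeline on a cohort bundle: probe filtering,
#' unsupervised two-cluster discovery on methylation and on
#' variance-stabilized expression, cluster concordance, per-probe
#' differential methylation with CGI / sub-region categorization and
#' chi-square association, Methyl-Set extraction, TRR annotation,
#' negative-binomial differential expression, both correlation-integration
#' cascades, broad / strict panel distillation, panel-based re-clustering
#' validation, and — when the sample table carries `pfs_months` and
#' `event` — the Kaplan-Meier / log-rank survival comparison between the
#' discovered clusters. Rerunning with the same input and thresholds
#' reproduces an identical report.
#'
#' @param cohort A `methx_cohort` bundle ([simulate_cohort()] or
#'   [read_cohort()]), or a [sim_config()] to simulate one.
#' @param thresholds [default_thresholds()] list.
#' @param out_dir Optional directory; when given, all stage outputs and
#'   the JSON report are written there.
#' @return An object of class `methx_report`: a list with a `counts`
#'   scalar summary (see [glance()]), the per-stage result objects under
#'   `stages`, and the thresholds used.
#' @export
run_pipeline <- function(cohort, thresholds = default_thresholds(),
                         out_dir = NULL) {
  if (inherits(cohort, "methx_sim_config")) {
    cohort <- simulate_cohort(cohort)
  }
  if (!inherits(cohort, "methx_cohort")) {
    abort("`cohort` must be a methx_cohort or a sim_config")
  }
  aligned <- align_samples(cohort$m, cohort$counts, cohort$samples)
  det <- cohort$detection_p[, colnames(aligned$methyl), drop = FALSE]

  filt <- filter_probes(aligned$methyl, det, cohort$manifest,
                        snp_flags = cohort$snp_flags,
                        cross_reactive = cohort$cross_reactive)
  m <- filt$m
  counts <- aligned$counts

  cl_m <- assign_two_clusters(m)
  vst <- vst_counts(counts)
  cl_e <- assign_two_clusters(vst)
  conc <- cluster_concordance(cl_m, cl_e)

  dmps <- call_dmps(m, cl_m, alpha = thresholds$dmp_alpha)
  cats <- categorize_dmps(dmps, cohort$manifest)
  chi_cgi <- tryCatch({
    tab <- as.matrix(cats$cgi[, c("hypo_B", "hyper_B")])
    chi_square_association(tab)$p
  }, error = function(e) NA_real_)

  sets <- extract_methyl_sets(dmps, m, cl_m)
  stopifnot(!anyDuplicated(sets$probe_id))  # Set1 and Set2 are disjoint
  trr <- trr_probes(sets$probe_id, cohort$manifest)

  degs <- call_degs(counts, cl_e, alpha = thresholds$deg_alpha,
                    lfc_min = thresholds$lfc_min)

  app1 <- correlate_methyl_sets(sets, cohort$manifest, m, degs, counts,
                                cl_m, r_min = thresholds$r_min,
                                alpha = thresholds$corr_alpha)
  panels <- distill_panels(degs, cohort$manifest, sets, m, counts, cl_e,
                           r_min = thresholds$r_min,
                           alpha = thresholds$corr_alpha)
  quad <- quadrant_counts(panels$records)

  deg_count <- sum(degs$is_deg)
  stopifnot(nrow(panels$strict) <= nrow(panels$broad),
            nrow(panels$broad) <= max(deg_count, 1),
            quad$negative + quad$positive == quad$significant)

  recluster <- NULL
  if (nrow(panels$strict) >= 2) {
    recluster <- panel_reclustering(panels$strict, m, counts, cl_m)
  } else if (nrow(panels$broad) >= 2) {
    recluster <- panel_reclustering(panels$broad, m, counts, cl_m)
  }

  surv <- NULL
  if (all(c("pfs_months", "event") %in% names(aligned$samples))) {
    surv <- compare_pfs(aligned$samples, cl_m)
  }

  dmp_tab <- dplyr::filter(dmps, .data$is_dmp)
  counts_out <- list(
    n_samples = ncol(m),
    n_probes_input = nrow(aligned$methyl),
    n_probes_retained = nrow(m),
    cluster_size_a = sum(cl_m$cluster == "A"),
    cluster_size_b = sum(cl_m$cluster == "B"),
    cluster_silhouette_methylation = attr(cl_m, "silhouette"),
    cluster_silhouette_expression = attr(cl_e, "silhouette"),
    cluster_concordance_ari = conc$ari,
    cluster_exact_match = conc$exact_match,
    dmp_count = nrow(dmp_tab),
    dmp_hypo_a = sum(dmp_tab$status_a == "hypomethylated"),
    dmp_hyper_a = sum(dmp_tab$status_a == "hypermethylated"),
    dmp_hypo_b = sum(dmp_tab$status_b == "hypomethylated"),
    dmp_hyper_b = sum(dmp_tab$status_b == "hypermethylated"),
    chi_square_cgi_p = chi_cgi,
    set1_size = sum(sets$set == "Set1"),
    set2_size = sum(sets$set == "Set2"),
    trr_pair_count = nrow(trr),
    trr_probe_count = dplyr::n_distinct(trr$probe_id),
    trr_gene_count = dplyr::n_distinct(trr$gene),
    deg_count = deg_count,
    deg_up = sum(degs$is_deg & degs$direction == "up", na.rm = TRUE),
    deg_down = sum(degs$is_deg & degs$direction == "down", na.rm = TRUE),
    pair_count = nrow(panels$records),
    significant_pairs = quad$significant,
    negative_pairs = quad$negative,
    positive_pairs = quad$positive,
    broad_panel_size = nrow(panels$broad),
    strict_panel_size = nrow(panels$strict),
    recluster_methylation_ari =
      if (is.null(recluster)) NA_real_ else recluster$methylation$ari,
    recluster_expression_ari =
      if (is.null(recluster)) NA_real_ else recluster$expression$ari,
    recluster_exact_match = if (is.null(recluster)) NA else {
      recluster$methylation$exact_match && recluster$expression$exact_match
    },
    median_pfs_a = if (is.null(surv)) NA_real_ else surv$median_a,
    median_pfs_b = if (is.null(surv)) NA_real_ else surv$median_b,
    logrank_p = if (is.null(surv)) NA_real_ else surv$logrank$p)

  # per-cluster hypo + hyper counts partition the DMP set
  stopifnot(counts_out$dmp_hypo_a + counts_out$dmp_hyper_a ==
              counts_out$dmp_count,
            counts_out$dmp_hypo_b + counts_out$dmp_hyper_b ==
              counts_out$dmp_count)

  report <- structure(
    list(counts = counts_out,
         stages = list(filter = filt$report, clustering_methylation = cl_m,
                       clustering_expression = cl_e, dmps = dmps,
                       categories = cats, methyl_sets = sets, trr = trr,
                       degs = degs, approach1 = app1, panels = panels,
                       quadrants = quad, reclustering = recluster,
                       survival = surv),
         thresholds = thresholds,
         version = as.character(utils::packageVersion("methxpanel")),
         config_hash = rlang::hash(list(thresholds,
                                        cohort$config %||% NA))),
    class = "methx_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  st <- report$stages
  readr::write_tsv(st$dmps, file.path(out_dir, "dmps.tsv"))
  readr::write_tsv(st$degs, file.path(out_dir, "degs.tsv"))
  readr::write_tsv(st$methyl_sets, file.path(out_dir, "methyl_sets.tsv"))
  readr::write_tsv(st$trr, file.path(out_dir, "trr_pairs.tsv"))
  if (nrow(st$panels$records) > 0) {
    readr::write_tsv(st$panels$records,
                     file.path(out_dir, "correlations.tsv"))
  }
  flat <- function(p) dplyr::mutate(
    p, probes = vapply(.data$probes, paste, character(1), collapse = ";"))
  if (nrow(st$panels$broad) > 0) {
    readr::write_tsv(flat(st$panels$broad),
                     file.path(out_dir, "panel_broad.tsv"))
  }
  if (nrow(st$panels$strict) > 0) {
    readr::write_tsv(flat(st$panels$strict),
                     file.path(out_dir, "panel_strict.tsv"))
  }
  readr::write_tsv(st$clustering_methylation,
                   file.path(out_dir, "labels_methylation.tsv"))
  readr::write_tsv(st$clustering_expression,
                   file.path(out_dir, "labels_expression.tsv"))
  jsonlite::write_json(report$counts,
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.methx_report <- function(x, ...) {
  co <- x$counts
  cat("<methx_report>\n")
  cat(sprintf("  clusters: %d (A) + %d (B); concordance ARI %.3f, exact match %s\n",
              co$cluster_size_a, co$cluster_size_b,
              co$cluster_concordance_ari, co$cluster_exact_match))
  cat(sprintf("  DMPs: %d (Set1 %d, Set2 %d); DEGs: %d (%d up, %d down)\n",
              co$dmp_count, co$set1_size, co$set2_size, co$deg_count,
              co$deg_up, co$deg_down))
  cat(sprintf("  pairs: %d tested, %d significant (%d negative); panels: broad %d, strict %d\n",
              co$pair_count, co$significant_pairs, co$negative_pairs,
              co$broad_panel_size, co$strict_panel_size))
  if (!is.na(co$median_pfs_a) || !is.na(co$median_pfs_b)) {
    cat(sprintf("  PFS medians: %s vs %s months; log-rank p = %s\n",
                format(co$median_pfs_a, digits = 4),
                format(co$median_pfs_b, digits = 4),
                format(co$logrank_p, digits = 3)))
  }
  invisible(x)
}
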