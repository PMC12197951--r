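#' Generate a synthetic probe manifest
#'
#' Builds an Illumina-manifest-like annotation table for the synthetic
#' cohort: every probe gets a chromosome, a 1-based position, one CpG-island
#' relation, and one gene sub-region per annotated gene. A configurable
#' fraction of probes annotates to two genes. Planted panel genes receive
#' two dedicated sign-consistent probes in transcriptional-regulatory-region
#' (TRR) sub-regions (TSS1500 / TSS200 / 5'UTR / 1stExon), so the
#' methylation-expression coupling downstream acts through realistic
#' promoter-region annotation.
#'
#' @param config A [sim_config()] object; requires `n_probes >= n_genes`.
#' @return A tibble with one row per (probe, gene) pair and columns
#'   `probe_id`, `chrom`, `pos`, `gene`, `subregion`, `cgi_relation`.
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "methx_sim_config"))
  if (config$n_probes < config$n_genes) {
    abort("`n_probes` must be at least `n_genes`")
  }
  plan <- sim_plan(config)
  set.seed(sub_seed(config$seed, "manifest"))
  n_probes <- config$n_probes
  n_genes <- config$n_genes

  # gene assignment: dedicated probes belong to their panel gene; remaining
  # probes cover every gene (shuffled round-robin fill)
  gene_idx <- rep(NA_integer_, n_probes)
  dedicated_probes <- integer(0)
  for (d in plan$dedicated) {
    gene_idx[d$probes] <- d$gene
    dedicated_probes <- c(dedicated_probes, d$probes)
  }
  if (length(plan$breaker_idx) > 0) {
    gene_idx[plan$breaker_idx] <- plan$non_strict_idx
    dedicated_probes <- c(dedicated_probes, plan$breaker_idx)
  }
  free <- which(is.na(gene_idx))
  gene_idx[free] <- sample(rep_len(seq_len(n_genes), length(free)))

  # sub-regions: dedicated probes are TRR; ordinary probes of panel genes
  # and non-dedicated sign-consistent probes are kept out of the TRR so the
  # planted panel truth stays exact; everything else draws from the full
  # vocabulary at array-like proportions
  trr_prob <- c(0.27, 0.15, 0.49, 0.09)
  non_trr <- c("Body", "ExonBnd", "3'UTR")
  full_prob <- c(0.13, 0.09, 0.11, 0.05, 0.45, 0.03, 0.14)
  set_probes <- c(plan$set1_idx, plan$set2_idx)
  subregion <- character(n_probes)
  is_dedicated <- seq_len(n_probes) %in% dedicated_probes
  for (i in seq_len(n_probes)) {
    if (is_dedicated[i]) {
      subregion[i] <- sample(TRR_SUBREGIONS, 1, prob = trr_prob)
    } else if (gene_idx[i] %in% plan$panel_idx || i %in% set_probes) {
      subregion[i] <- sample(non_trr, 1, prob = c(0.8, 0.05, 0.15))
    } else {
      subregion[i] <- sample(SUBREGIONS, 1, prob = full_prob)
    }
  }

  cgi <- sample(CGI_RELATIONS, n_probes, replace = TRUE,
                prob = c(0.17, 0.06, 0.06, 0.025, 0.025, 0.66))
  chrom <- sample(paste0("chr", 1:22), n_probes, replace = TRUE)
  pos <- sample.int(1e8, n_probes, replace = TRUE)

  manifest <- tibble(
    probe_id = plan$probe_ids,
    chrom = chrom, pos = pos,
    gene = plan$gene_ids[gene_idx],
    subregion = subregion, cgi_relation = cgi)

  # second-gene annotations for a fraction of ordinary probes
  eligible <- which(!is_dedicated & !(gene_idx %in% plan$panel_idx) &
                      !(seq_len(n_probes) %in% set_probes))
  multi <- eligible[runif(length(eligible)) < config$frac_multi_gene]
  if (length(multi) > 0) {
    non_panel_genes <- setdiff(seq_len(n_genes), plan$panel_idx)
    second <- vapply(multi, function(i) {
      pick <- setdiff(non_panel_genes, gene_idx[i])
      if (length(pick) == 0) NA_integer_ else sample(pick, 1)
    }, integer(1))
    keep <- !is.na(second)
    if (any(keep)) {
      extra <- tibble(
        probe_id = plan$probe_ids[multi[keep]],
        chrom = chrom[multi[keep]], pos = pos[multi[keep]],
        gene = plan$gene_ids[second[keep]],
        subregion = sample(SUBREGIONS, sum(keep), replace = TRUE,
                           prob = full_prob),
        cgi_relation = cgi[multi[keep]])
      manifest <- dplyr::bind_rows(manifest, extra)
    }
  }
  manifest <- dplyr::arrange(manifest, .data$probe_id, .data$gene)
  validate_manifest(manifest)
}

#' Simulate the methylation matrix of the synthetic cohort
#'
#' Produces an M-value matrix (probes x samples) with two latent clusters.
#' Non-differential probes share one baseline mean across clusters; planted
#' DMPs have a between-cluster mean gap of `delta_m`; Set1 / Set2 probes are
#' placed symmetrically around zero so cluster A and cluster B values fall
#' on strictly opposite sides of zero. Sign-consistency flags in the
#' returned truth table are assigned only after verifying the realized
#' (noisy) values, so set-extraction tests can assert exact equality.
#'
#' @param config A [sim_config()] object.
#' @param manifest Manifest from [generate_manifest()] (used for id
#'   consistency checks).
#' @return A list with elements `m` (M-value matrix), `detection_p`
#'   (matching detection P-value matrix, all passing), `samples` (tibble
#'   with `sample_id`, `cluster_truth`) and `probes` (truth tibble with
#'   `probe_id`, `dmp_flag`, `set1_flag`, `set2_flag`).
#' @export
simulate_methylation <- function(config, manifest) {
  stopifnot(inherits(config, "methx_sim_config"))
  plan <- sim_plan(config)
  if (!setequal(unique(manifest$probe_id), plan$probe_ids)) {
    abort("manifest probes do not match the configuration")
  }
  if (config$frac_dmp > 0 && config$delta_m <= 0) {
    abort("`delta_m` must be positive when `frac_dmp` > 0")
  }
  set.seed(sub_seed(config$seed, "methylation"))
  n_probes <- config$n_probes
  n_samples <- length(plan$sample_ids)
  in_a <- plan$cluster == "A"

  mu_a <- rnorm(n_probes, 0, 1.5)
  mu_b <- mu_a
  dmp <- logical(n_probes); dmp[plan$dmp_idx] <- TRUE
  set1 <- logical(n_probes); set1[plan$set1_idx] <- TRUE
  set2 <- logical(n_probes); set2[plan$set2_idx] <- TRUE
  other_dmp <- dmp & !set1 & !set2
  half <- config$delta_m / 2
  mu_a[set1] <- -half; mu_b[set1] <- half
  mu_a[set2] <- half;  mu_b[set2] <- -half
  if (any(other_dmp)) {
    # same-sign cluster means separated by delta_m: these DMPs keep the
    # same methylation state in both clusters (the typical DMP majority)
    s <- sample(c(-1, 1), sum(other_dmp), replace = TRUE)
    mu_a[other_dmp] <- s * 0.5
    mu_b[other_dmp] <- s * (0.5 + config$delta_m)
  }

  mu <- matrix(0, n_probes, n_samples)
  mu[, in_a] <- mu_a
  mu[, !in_a] <- mu_b
  m <- mu + matrix(rnorm(n_probes * n_samples, 0, config$m_noise_sd),
                   n_probes, n_samples)
  dimnames(m) <- list(plan$probe_ids, plan$sample_ids)
  detection_p <- matrix(runif(n_probes * n_samples, 0, 0.009),
                        n_probes, n_samples, dimnames = dimnames(m))

  # post-hoc verification: flags only where the realized values satisfy
  # the strict inequalities
  max_a <- apply(m[, in_a, drop = FALSE], 1, max)
  min_a <- apply(m[, in_a, drop = FALSE], 1, min)
  max_b <- apply(m[, !in_a, drop = FALSE], 1, max)
  min_b <- apply(m[, !in_a, drop = FALSE], 1, min)
  set1_ok <- set1 & (max_a < 0) & (min_b > 0)
  set2_ok <- set2 & (min_a > 0) & (max_b < 0)

  list(
    m = m, detection_p = detection_p,
    samples = tibble(sample_id = plan$sample_ids,
                     cluster_truth = plan$cluster),
    probes = tibble(probe_id = plan$probe_ids, dmp_flag = dmp,
                    set1_flag = set1_ok, set2_flag = set2_ok))
}

#' Simulate RNA-seq counts coupled to TRR methylation
#'
#' Draws negative-binomial counts (genes x samples) with per-sample size
#' factors. Planted non-panel DEGs get a fixed log2 fold-change between the
#' clusters; planted panel genes instead have their per-sample log2 mean
#' tied linearly (slope `coupling_strength`, <= 0) to the realized TRR
#' median M-value of the gene, producing negative methylation-expression
#' correlation and an induced fold-change of about
#' `-coupling_strength * delta_m`.
#'
#' @param config A [sim_config()] object.
#' @param manifest Manifest from [generate_manifest()].
#' @param methyl Result of [simulate_methylation()] (same config).
#' @return A list with `counts` (integer matrix genes x samples),
#'   `size_factors_true` (the planted per-sample factors, geometric mean 1)
#'   and `genes` (truth tibble with `gene_id`, `deg_flag`, `true_log2fc`,
#'   `panel_flag`, `strict_panel_flag`).
#' @export
simulate_expression <- function(config, manifest, methyl) {
  stopifnot(inherits(config, "methx_sim_config"))
  if (config$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  plan <- sim_plan(config)
  if (!identical(rownames(methyl$m), plan$probe_ids)) {
    abort("methylation matrix does not match the configuration")
  }
  set.seed(sub_seed(config$seed, "expression"))
  n_genes <- config$n_genes
  n_samples <- length(plan$sample_ids)
  in_b <- plan$cluster == "B"

  base <- runif(n_genes, 3, 9)
  sf <- exp(rnorm(n_samples, 0, 0.15))
  sf <- sf / exp(mean(log(sf)))

  deg <- logical(n_genes); deg[plan$deg_idx] <- TRUE
  panel <- logical(n_genes); panel[plan$panel_idx] <- TRUE
  strict <- logical(n_genes); strict[plan$strict_idx] <- TRUE
  up <- logical(n_genes); up[plan$up_idx] <- TRUE

  l2 <- matrix(base, n_genes, n_samples)
  lfc <- numeric(n_genes)
  ordinary_deg <- deg & !panel
  if (any(ordinary_deg)) {
    sgn <- ifelse(up[ordinary_deg], 1, -1)
    lfc[ordinary_deg] <- sgn * config$log2fc_planted
    l2[ordinary_deg, in_b] <- l2[ordinary_deg, in_b] +
      sgn * config$log2fc_planted
  }
  if (any(panel)) {
    for (g in which(panel)) {
      med <- gene_trr_median_m(methyl$m, manifest, plan$gene_ids[g])
      l2[g, ] <- base[g] + config$coupling_strength * med
      lfc[g] <- config$coupling_strength *
        (median(med[in_b]) - median(med[!in_b]))
    }
  }

  mu <- sweep(2^l2, 2, sf, `*`)
  counts <- if (config$nb_dispersion == 0) {
    matrix(rpois(length(mu), mu), n_genes, n_samples)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           n_genes, n_samples)
  }
  dimnames(counts) <- list(plan$gene_ids, plan$sample_ids)
  storage.mode(counts) <- "integer"

  list(
    counts = counts, size_factors_true = setNames(sf, plan$sample_ids),
    genes = tibble(gene_id = plan$gene_ids, deg_flag = deg | panel,
                   true_log2fc = lfc, panel_flag = panel,
                   strict_panel_flag = strict))
}

#' Simulate progression-free survival for the synthetic cohort
#'
#' Event times are exponential with cluster-specific medians (rate =
#' log(2) / median). A fraction of samples, drawn independently of cluster,
#' is censored at a uniform fraction of its event time.
#'
#' @param config A [sim_config()] object.
#' @param samples Sample truth tibble (with `sample_id`, `cluster_truth`),
#'   e.g. from [simulate_methylation()].
#' @return A tibble with `sample_id`, `cluster_truth`, `pfs_months`,
#'   `event` (1 = progression observed, 0 = censored) and
#'   `true_event_time`.
#' @export
simulate_survival <- function(config, samples) {
  stopifnot(inherits(config, "methx_sim_config"))
  if (config$median_pfs_a <= 0 || config$median_pfs_b <= 0) {
    abort("PFS medians must be positive")
  }
  if (!all(c("sample_id", "cluster_truth") %in% names(samples))) {
    abort("`samples` needs `sample_id` and `cluster_truth` columns")
  }
  set.seed(sub_seed(config$seed, "survival"))
  n <- nrow(samples)
  rate <- ifelse(samples$cluster_truth == "A",
                 log(2) / config$median_pfs_a,
                 log(2) / config$median_pfs_b)
  t_event <- rexp(n, rate)
  censored <- runif(n) < config$censor_frac
  obs <- ifelse(censored, runif(n) * t_event, t_event)
  tibble(sample_id = samples$sample_id,
         cluster_truth = samples$cluster_truth,
         pfs_months = obs, event = as.integer(!censored),
         true_event_time = t_event)
}

#' Simulate a complete coupled methylome-transcriptome-survival cohort
#'
#' Convenience wrapper running [generate_manifest()],
#' [simulate_methylation()], [simulate_expression()] and
#' [simulate_survival()] under one config, returning everything the
#' pipeline consumes plus the full ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `methx_cohort` with elements `manifest`, `m`,
#'   `detection_p`, `counts`, `samples` (sample table incl. survival),
#'   `truth` (list: `samples`, `probes`, `genes`, `size_factors`) and
#'   `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_probes = 300, n_genes = 80))
#' dim(cohort$m)
simulate_cohort <- function(config = sim_config()) {
  manifest <- generate_manifest(config)
  methyl <- simulate_methylation(config, manifest)
  expr <- simulate_expression(config, manifest, methyl)
  surv <- simulate_survival(config, methyl$samples)
  samples <- dplyr::select(surv, "sample_id", "cluster_truth",
                           "pfs_months", "event")
  structure(
    list(manifest = manifest, m = methyl$m,
         detection_p = methyl$detection_p, counts = expr$counts,
         samples = samples,
         truth = list(samples = surv, probes = methyl$probes,
                      genes = expr$genes,
                      size_factors = expr$size_factors_true),
         config = config),
    class = "methx_cohort")
}

#' @export
print.methx_cohort <- function(x, ...) {
  cat("<methx_cohort>\n")
  cat(sprintf("  %d probes x %d samples (M-values); %d genes (counts)\n",
              nrow(x$m), ncol(x$m), nrow(x$counts)))
  cat(sprintf("  planted: %d DMPs (%d Set1, %d Set2), %d DEGs, %d panel genes (%d strict)\n",
              sum(x$truth$probes$dmp_flag), sum(x$truth$probes$set1_flag),
              sum(x$truth$probes$set2_flag), sum(x$truth$genes$deg_flag),
              sum(x$truth$genes$panel_flag),
              sum(x$truth$genes$strict_panel_flag)))
  invisible(x)
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits `m_values.tsv`, `detection_p.tsv`, `counts.tsv`, `manifest.csv`,
#' `samples.tsv`, `truth_probes.tsv` and `truth_genes.tsv` into a
#' directory, in the formats the package's readers consume, with identical
#' sample order across files. Writing the same seeded cohort twice gives
#' identical files.
#'
#' @param cohort A `methx_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_fixture <- function(cohort, dir) {
  if (!inherits(cohort, "methx_cohort")) {
    abort("`cohort` must be a methx_cohort")
  }
  needed <- c("manifest", "m", "detection_p", "counts", "samples")
  if (any(vapply(cohort[needed], is.null, logical(1)))) {
    abort("cohort bundle is incomplete; nothing written")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    m_values = file.path(dir, "m_values.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    counts = file.path(dir, "counts.tsv"),
    manifest = file.path(dir, "manifest.csv"),
    samples = file.path(dir, "samples.tsv"),
    truth_probes = file.path(dir, "truth_probes.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"))
  write_omics_matrix(cohort$m, paths["m_values"])
  write_omics_matrix(cohort$detection_p, paths["detection_p"])
  write_omics_matrix(cohort$counts, paths["counts"])
  readr::write_csv(cohort$manifest, paths["manifest"])
  readr::write_tsv(cohort$samples, paths["samples"])
  readr::write_tsv(cohort$truth$probes, paths["truth_probes"])
  readr::write_tsv(cohort$truth$genes, paths["truth_genes"])
  invisible(paths)
}
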