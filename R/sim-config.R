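#' Configuration for the synthetic two-cluster cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: two latent
#' sample clusters (default 9 + 6, the cohort split the pipeline is designed
#' around), a fraction of differentially methylated probes of which sub-sets
#' are made strictly sign-consistent on the M-value scale, negative-binomial
#' RNA-seq counts with planted differentially expressed genes, panel genes
#' whose expression is negatively coupled to their transcriptional-regulatory
#' -region (TRR) methylation, and exponential progression-free-survival times
#' with cluster-dependent medians.
#'
#' @param n_samples_a,n_samples_b Sizes of latent clusters A and B.
#' @param n_probes,n_genes Number of methylation probes and of genes.
#' @param frac_dmp Fraction of probes planted as differentially methylated.
#' @param frac_set1,frac_set2 Fractions of the planted DMPs made strictly
#'   sign-consistent: Set1 probes have all cluster-A M-values below zero and
#'   all cluster-B M-values above zero; Set2 is the mirror image. Must sum
#'   to at most 1.
#' @param delta_m Between-cluster mean gap on the M-value scale for planted
#'   DMPs (sign-consistent probes sit at `-delta_m/2` / `+delta_m/2`).
#' @param m_noise_sd Standard deviation of i.i.d. Gaussian M-value noise.
#' @param nb_dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2); 0 gives the Poisson limit.
#' @param frac_deg Fraction of genes planted as differentially expressed.
#' @param log2fc_planted Absolute log2 fold-change of planted (non-panel)
#'   DEGs; must be >= 0.
#' @param frac_deg_up Fraction of planted DEGs up-regulated in cluster B.
#' @param coupling_strength Slope (<= 0) of the gene log2-expression on the
#'   gene's per-sample TRR median M-value, applied to panel genes only.
#'   The induced panel log2 fold-change is about
#'   `-coupling_strength * delta_m`.
#' @param frac_multi_gene Fraction of ordinary probes annotated to a second
#'   gene.
#' @param frac_panel_strict Fraction of planted panel genes whose entire TRR
#'   is sign-consistent (the "strict" panel); the remaining panel genes get
#'   one additional non-differential TRR probe that breaks whole-TRR
#'   consistency, so they are recoverable by the broad but not the strict
#'   cascade.
#' @param median_pfs_a,median_pfs_b Median progression-free survival per
#'   cluster, in months.
#' @param censor_frac Fraction of samples censored (in `[0, 1)`).
#' @param seed Integer seed; one global seed drives a named sub-stream per
#'   component, so identical configs give bit-identical cohorts.
#'
#' @return An object of class `methx_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 500, n_genes = 100, seed = 7)
#' cfg$n_samples_a
sim_config <- function(n_samples_a = 9, n_samples_b = 6,
                       n_probes = 2000, n_genes = 600,
                       frac_dmp = 0.1, frac_set1 = 0.1, frac_set2 = 0.3,
                       delta_m = 4, m_noise_sd = 0.5,
                       nb_dispersion = 0.1, frac_deg = 0.1,
                       log2fc_planted = 3, frac_deg_up = 0.8,
                       coupling_strength = -1,
                       frac_multi_gene = 0.1, frac_panel_strict = 0.25,
                       median_pfs_a = 140.1, median_pfs_b = 25.1,
                       censor_frac = 0.2, seed = 1L) {
  check_count(n_samples_a, "n_samples_a", 1L)
  check_count(n_samples_b, "n_samples_b", 1L)
  if (n_samples_a + n_samples_b < 4) {
    abort("need at least 4 samples in total")
  }
  check_count(n_probes, "n_probes", 1L)
  check_count(n_genes, "n_genes", 1L)
  for (nm in c("frac_dmp", "frac_set1", "frac_set2", "frac_deg",
               "frac_deg_up", "frac_multi_gene", "frac_panel_strict")) {
    check_fraction(get(nm), nm)
  }
  if (frac_set1 + frac_set2 > 1) {
    abort("`frac_set1` + `frac_set2` must not exceed 1")
  }
  check_fraction(censor_frac, "censor_frac")
  if (censor_frac >= 1) abort("`censor_frac` must be below 1")
  if (log2fc_planted < 0) abort("`log2fc_planted` must be >= 0")
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (m_noise_sd < 0) abort("`m_noise_sd` must be >= 0")
  if (coupling_strength > 0) abort("`coupling_strength` must be <= 0")
  if (median_pfs_a <= 0 || median_pfs_b <= 0) {
    abort("PFS medians must be positive")
  }
  check_count(seed, "seed")
  structure(
    list(n_samples_a = as.integer(n_samples_a),
         n_samples_b = as.integer(n_samples_b),
         n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
         frac_dmp = frac_dmp, frac_set1 = frac_set1, frac_set2 = frac_set2,
         delta_m = delta_m, m_noise_sd = m_noise_sd,
         nb_dispersion = nb_dispersion, frac_deg = frac_deg,
         log2fc_planted = log2fc_planted, frac_deg_up = frac_deg_up,
         coupling_strength = coupling_strength,
         frac_multi_gene = frac_multi_gene,
         frac_panel_strict = frac_panel_strict,
         median_pfs_a = median_pfs_a, median_pfs_b = median_pfs_b,
         censor_frac = censor_frac, seed = as.integer(seed)),
    class = "methx_sim_config")
}

#' @export
print.methx_sim_config <- function(x, ...) {
  cat("<methx_sim_config>\n")
  cat(sprintf("  samples: %d (A) + %d (B); probes: %d; genes: %d\n",
              x$n_samples_a, x$n_samples_b, x$n_probes, x$n_genes))
  cat(sprintf("  DMPs: %.0f%% (Set1 %.0f%%, Set2 %.0f%% of DMPs), delta_m = %g, noise sd = %g\n",
              100 * x$frac_dmp, 100 * x$frac_set1, 100 * x$frac_set2,
              x$delta_m, x$m_noise_sd))
  cat(sprintf("  DEGs: %.0f%% at |log2FC| = %g; coupling = %g; NB dispersion = %g\n",
              100 * x$frac_deg, x$log2fc_planted, x$coupling_strength,
              x$nb_dispersion))
  cat(sprintf("  PFS medians: %g vs %g months; censoring %.0f%%; seed %d\n",
              x$median_pfs_a, x$median_pfs_b, 100 * x$censor_frac, x$seed))
  invisible(x)
}

# Deterministic planted structure derived from a config (no randomness):
# which probes are DMPs / Set1 / Set2, which genes are DEGs / panel genes,
# and the dedicated probe -> panel gene assignments.
sim_plan <- function(config) {
  stopifnot(inherits(config, "methx_sim_config"))
  n_probes <- config$n_probes
  n_genes <- config$n_genes
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  n_samples <- config$n_samples_a + config$n_samples_b
  sample_ids <- sprintf("ACP%02d", seq_len(n_samples))
  cluster <- rep(c("A", "B"), c(config$n_samples_a, config$n_samples_b))

  n_dmp <- round(config$frac_dmp * n_probes)
  n_set1 <- round(config$frac_set1 * n_dmp)
  n_set2 <- round(config$frac_set2 * n_dmp)
  dmp_idx <- seq_len(n_dmp)
  set1_idx <- seq_len(n_set1)
  set2_idx <- if (n_set2 > 0) n_set1 + seq_len(n_set2) else integer(0)

  n_deg <- round(config$frac_deg * n_genes)
  n_up <- round(config$frac_deg_up * n_deg)
  up_idx <- seq_len(n_up)
  down_idx <- if (n_deg > n_up) (n_up + 1L):n_deg else integer(0)

  n_panel_up <- min(n_up, floor(n_set2 / 2))
  n_panel_dn <- min(length(down_idx), floor(n_set1 / 2))
  panel_up_idx <- up_idx[seq_len(n_panel_up)]
  panel_dn_idx <- down_idx[seq_len(n_panel_dn)]
  panel_idx <- c(panel_up_idx, panel_dn_idx)

  # dedicated sign-consistent TRR probes, two per panel gene
  dedicated <- list()
  if (n_panel_up > 0) {
    for (j in seq_len(n_panel_up)) {
      dedicated[[length(dedicated) + 1L]] <-
        list(gene = panel_up_idx[j], probes = set2_idx[c(2 * j - 1, 2 * j)],
             set = "Set2")
    }
  }
  if (n_panel_dn > 0) {
    for (j in seq_len(n_panel_dn)) {
      dedicated[[length(dedicated) + 1L]] <-
        list(gene = panel_dn_idx[j], probes = set1_idx[c(2 * j - 1, 2 * j)],
             set = "Set1")
    }
  }

  # strict subset: first frac_panel_strict of each direction group
  # (at least one strict gene whenever the panel is non-empty)
  n_strict_up <- round(config$frac_panel_strict * n_panel_up)
  n_strict_dn <- round(config$frac_panel_strict * n_panel_dn)
  if (length(panel_idx) > 0 && n_strict_up + n_strict_dn == 0) {
    if (n_panel_up > 0) n_strict_up <- 1L else n_strict_dn <- 1L
  }
  strict_idx <- c(panel_up_idx[seq_len(n_strict_up)],
                  panel_dn_idx[seq_len(n_strict_dn)])

  # non-strict panel genes get one extra non-differential TRR probe,
  # taken from the top of the probe index range (never DMPs there as long
  # as frac_dmp < 1)
  non_strict_idx <- setdiff(panel_idx, strict_idx)
  breaker <- integer(0)
  if (length(non_strict_idx) > 0) {
    breaker <- n_probes - seq_along(non_strict_idx) + 1L
    if (any(breaker <= n_dmp)) {
      abort("not enough non-DMP probes to break whole-TRR consistency; lower frac_dmp or frac of panel genes")
    }
  }

  list(probe_ids = probe_ids, gene_ids = gene_ids,
       sample_ids = sample_ids, cluster = cluster,
       dmp_idx = dmp_idx, set1_idx = set1_idx, set2_idx = set2_idx,
       deg_idx = seq_len(n_deg), up_idx = up_idx, down_idx = down_idx,
       panel_idx = panel_idx, panel_up_idx = panel_up_idx,
       panel_dn_idx = panel_dn_idx, strict_idx = strict_idx,
       non_strict_idx = non_strict_idx, breaker_idx = breaker,
       dedicated = dedicated)
}
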