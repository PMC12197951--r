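#' Probe-level quality filtering
#'
#' Applies the standard EPIC-array probe exclusion rules, in order: probes
#' failing detection (P > 0.01 in any sample), probes on sex chromosomes,
#' probes overlapping SNPs, and cross-reactive probes. Each removed probe
#' is counted once, under the first rule that removes it.
#'
#' @param methyl M-value matrix (probes x samples).
#' @param detection_p Detection P-value matrix aligned to `methyl`.
#' @param manifest Probe manifest tibble (for chromosome lookup).
#' @param snp_flags Optional character vector of SNP-overlapping probe ids.
#' @param cross_reactive Optional character vector of cross-reactive probe
#'   ids.
#' @param p_max Detection threshold (default 0.01).
#' @return A list with `m` (filtered matrix) and `report` (tibble of per-
#'   rule removal counts plus the retained total; removed + retained equals
#'   the input probe count).
#' @export
filter_probes <- function(methyl, detection_p, manifest, snp_flags = NULL,
                          cross_reactive = NULL, p_max = 0.01) {
  check_feature_matrix(methyl, "methylation matrix")
  if (!identical(dim(methyl), dim(detection_p)) ||
      !identical(rownames(methyl), rownames(detection_p)) ||
      !identical(colnames(methyl), colnames(detection_p))) {
    abort("detection P matrix is not aligned to the methylation matrix")
  }
  probes <- rownames(methyl)
  fail_det <- apply(detection_p > p_max, 1, any)
  sex_probes <- unique(manifest$probe_id[manifest$chrom %in% SEX_CHROMS])
  on_sex <- probes %in% sex_probes
  is_snp <- probes %in% (snp_flags %||% character(0))
  is_xr <- probes %in% (cross_reactive %||% character(0))

  rule <- rep(NA_character_, length(probes))
  rule[is_xr] <- "cross_reactive"
  rule[is_snp] <- "snp_overlap"
  rule[on_sex] <- "sex_chromosome"
  rule[fail_det] <- "detection_p"  # first-rule-wins: assigned last

  keep <- is.na(rule)
  rule_names <- c("detection_p", "sex_chromosome", "snp_overlap",
                  "cross_reactive")
  n_removed <- vapply(rule_names,
                      function(r) sum(rule == r, na.rm = TRUE), integer(1))
  report <- tibble(rule = c(rule_names, "retained"),
                   n = c(unname(n_removed), sum(keep)))
  list(m = methyl[keep, , drop = FALSE], report = report)
}

#' Convert between beta and M methylation scales
#'
#' M = log2(beta / (1 - beta)); beta = 2^M / (1 + 2^M). Beta values of
#' exactly 0 or 1 would map to infinite M and are an error.
#'
#' @param beta Beta values, strictly inside (0, 1).
#' @param m M-values (any finite real).
#' @return The converted vector.
#' @export
#' @examples
#' beta_to_m(0.8)  # 2
#' m_to_beta(0)    # 0.5
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) {
    abort("beta values must lie strictly inside (0, 1)")
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) abort("M-values must be finite")
  2^m / (1 + 2^m)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for count matrices: genes with any zero
#' count are excluded from the reference; each sample's factor is the
#' median over remaining genes of count / gene geometric mean.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_feature_matrix(counts, "count matrix")
  log_counts <- log(counts)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    abort("no gene with nonzero counts in every sample; size factors undefined")
  }
  log_geo <- rowMeans(log_counts[usable, , drop = FALSE])
  sf <- apply(log_counts[usable, , drop = FALSE], 2,
              function(col) exp(median(col - log_geo)))
  if (any(sf <= 0)) abort("non-positive size factor")
  sf
}

#' Shifted-log variance-stabilizing transform
#'
#' `log2(count / size_factor + 1)`, used as the clustering input for
#' expression data. This is a deterministic shifted log of size-factor-
#' normalized counts (not a fitted dispersion-trend transform); see the
#' methods vignette for the rationale.
#'
#' @param counts Count matrix (genes x samples).
#' @param sf Optional precomputed size factors; defaults to
#'   [size_factors()].
#' @return Real matrix of the same shape.
#' @export
vst_counts <- function(counts, sf = NULL) {
  sf <- sf %||% size_factors(counts)
  if (!identical(names(sf), colnames(counts))) {
    sf <- sf[colnames(counts)]
  }
  log2(sweep(counts, 2, sf, `/`) + 1)
}
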