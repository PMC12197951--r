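#' Mann-Whitney U test for two samples
#'
#' Rank-sum comparison of two groups. With `n_a + n_b <= 20` and no ties
#' the two-sided p-value is computed by exact enumeration of rank
#' assignments; otherwise the normal approximation with tie and continuity
#' correction is used. `u` is the U statistic of the first group, so
#' swapping the groups maps U to `n_a * n_b - U` at identical p.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A list with `u` and `p` (two-sided).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b) <= 20)
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE))
  list(u = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Multiplies the i-th smallest p-value by m/i and enforces monotonicity
#' from the largest rank down, capping at 1. Order-preserving; adjusted
#' values are never below the raw ones.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Per-probe differential methylation between two clusters
#'
#' Runs [mann_whitney()] on every probe's M-values between clusters A and
#' B, adjusts across all tested probes with [bh_adjust()], and classifies
#' each probe's methylation status per cluster by the sign of the cluster
#' median M-value (median below zero: hypomethylated; zero or above:
#' hypermethylated). Probes with adjusted p <= `alpha` are flagged DMPs.
#'
#' @param methyl M-value matrix (probes x samples).
#' @param labels Cluster labels ("A"/"B"): a `methx_clustering` tibble or
#'   named vector; each cluster needs at least 2 samples.
#' @param alpha DMP significance threshold on adjusted p (default 0.05).
#' @return A tibble with one row per probe: `probe_id`, `u`, `p_raw`,
#'   `p_adj`, `median_m_a`, `median_m_b`, `status_a`, `status_b`,
#'   `is_dmp`.
#' @export
call_dmps <- function(methyl, labels, alpha = 0.05) {
  check_feature_matrix(methyl, "methylation matrix")
  lab <- resolve_labels(labels, colnames(methyl))
  in_a <- lab == "A"
  if (sum(in_a) < 2 || sum(!in_a) < 2) {
    abort("each cluster needs at least 2 samples")
  }
  ma <- methyl[, in_a, drop = FALSE]
  mb <- methyl[, !in_a, drop = FALSE]
  res <- vapply(seq_len(nrow(methyl)), function(i) {
    mw <- mann_whitney(ma[i, ], mb[i, ])
    c(mw$u, mw$p)
  }, numeric(2))
  med_a <- apply(ma, 1, median)
  med_b <- apply(mb, 1, median)
  p_adj <- bh_adjust(res[2, ])
  tibble(
    probe_id = rownames(methyl),
    u = res[1, ], p_raw = res[2, ], p_adj = p_adj,
    median_m_a = med_a, median_m_b = med_b,
    status_a = ifelse(med_a < 0, "hypomethylated", "hypermethylated"),
    status_b = ifelse(med_b < 0, "hypomethylated", "hypermethylated"),
    is_dmp = p_adj <= alpha)
}

# Nonincreasing isotonic fit of y on the order of x (dispersion-mean trend)
iso_decreasing_trend <- function(x, y) {
  o <- order(x)
  fit <- rev(isoreg(rev(y[o]))$yf)
  out <- numeric(length(y))
  out[o] <- fit
  out
}

#' Negative-binomial Wald differential expression
#'
#' A self-contained NB Wald test between two clusters. Counts are
#' normalized by median-of-ratios [size_factors()]; per-cluster normalized
#' means carry a 0.5 pseudo-count and define `log2fc = log2(mean_B /
#' mean_A)`. Per-gene dispersions come from a within-cluster
#' method-of-moments estimate floored at 1e-8 and shrunk 50% toward a
#' monotone (nonincreasing) dispersion-mean trend. The Wald statistic is
#' `log2fc` over its delta-method standard error; p-values are two-sided
#' normal and BH-adjusted across tested genes. A gene is flagged
#' differentially expressed when `p_adj <= alpha` and `|log2fc| >=
#' lfc_min`. Genes with zero counts in every sample are excluded from
#' testing and reported with `tested = FALSE`.
#'
#' @param counts Count matrix (genes x samples).
#' @param labels Cluster labels ("A"/"B"); at least 2 samples per cluster.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param lfc_min Absolute log2 fold-change threshold (default 2).
#' @return A tibble with `gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p_raw`, `p_adj`, `is_deg`, `direction` ("up"/"down" in cluster B)
#'   and `tested`.
#' @export
call_degs <- function(counts, labels, alpha = 0.01, lfc_min = 2) {
  check_feature_matrix(counts, "count matrix")
  lab <- resolve_labels(labels, colnames(counts))
  in_a <- lab == "A"
  if (sum(in_a) < 2 || sum(!in_a) < 2) {
    abort("each cluster needs at least 2 samples")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  na <- sum(in_a); nb <- sum(!in_a)
  tested <- rowSums(counts) > 0

  q_a <- rowMeans(norm[, in_a, drop = FALSE]) + 0.5
  q_b <- rowMeans(norm[, !in_a, drop = FALSE]) + 0.5
  base_mean <- rowMeans(norm)
  log2fc <- log2(q_b / q_a)

  # method-of-moments dispersion from pooled within-cluster variance
  v_a <- apply(norm[, in_a, drop = FALSE], 1, var)
  v_b <- apply(norm[, !in_a, drop = FALSE], 1, var)
  v_pool <- ((na - 1) * v_a + (nb - 1) * v_b) / (na + nb - 2)
  mu_pool <- (na * (q_a - 0.5) + nb * (q_b - 0.5)) / (na + nb)
  alpha_mom <- pmax((v_pool - mu_pool) / pmax(mu_pool, 1e-8)^2, 1e-8)
  trend <- iso_decreasing_trend(base_mean[tested], alpha_mom[tested])
  disp <- alpha_mom
  disp[tested] <- 0.5 * alpha_mom[tested] + 0.5 * trend

  inv_sf_a <- mean(1 / sf[in_a]); inv_sf_b <- mean(1 / sf[!in_a])
  var_qa <- q_a * inv_sf_a / na + disp * q_a^2 / na
  var_qb <- q_b * inv_sf_b / nb + disp * q_b^2 / nb
  se <- sqrt(var_qa / q_a^2 + var_qb / q_b^2) / log(2)
  stat <- log2fc / se
  p_raw <- 2 * pnorm(-abs(stat))
  p_raw[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[tested] <- bh_adjust(p_raw[tested])

  tibble(
    gene_id = rownames(counts), base_mean = unname(base_mean),
    log2fc = unname(ifelse(tested, log2fc, NA_real_)),
    se = unname(ifelse(tested, se, NA_real_)),
    stat = unname(ifelse(tested, stat, NA_real_)),
    p_raw = unname(p_raw), p_adj = unname(p_adj),
    is_deg = unname(tested & !is.na(p_adj) & p_adj <= alpha &
                      abs(log2fc) >= lfc_min),
    direction = unname(ifelse(!tested, NA_character_,
                              ifelse(log2fc >= 0, "up", "down"))),
    tested = unname(tested))
}

#' Pearson chi-square association test
#'
#' Chi-square test of independence without continuity correction, with
#' `df = (r - 1)(c - 1)`. Any zero expected count is an error (merge
#' sparse categories first).
#'
#' @param tab Contingency table (matrix of non-negative counts).
#' @return A list with `statistic`, `df` and `p`.
#' @export
#' @examples
#' chi_square_association(matrix(c(10, 0, 0, 10), 2))  # statistic 20
chi_square_association <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("contingency table must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("zero expected count; merge sparse categories before testing")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
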