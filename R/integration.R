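#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the t-based two-sided p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom);
#' `|r| = 1` gives p = 0. Zero variance in either vector is an error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) abort("need equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance")
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(r = r, p = p)
}

# vectorized pearson r/p for rows of two aligned matrices
row_pearson <- function(xm, ym) {
  n <- ncol(xm)
  xz <- xm - rowMeans(xm)
  yz <- ym - rowMeans(ym)
  denom <- sqrt(rowSums(xz^2) * rowSums(yz^2))
  r <- ifelse(denom == 0, NA_real_, rowSums(xz * yz) / denom)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) >= 1, 0, 2 * pt(-abs(tt), n - 2))
  list(r = r, p = p)
}

quadrant_label <- function(probe_status_b, gene_direction_b) {
  paste0(ifelse(probe_status_b == "hypomethylated", "Hypo", "Hyper"),
         "_", ifelse(gene_direction_b == "up", "Up", "Down"))
}

#' Methylation-driven integration (Approach I)
#'
#' Starts from the sign-consistent Methyl-Set probes, takes their TRR
#' (probe, gene) pairs, and splits the annotated genes into (a) the overlap
#' with the DEGs — each labelled `typical` when the methylation change
#' predicts the expression change in cluster B (Set2/hypomethylated with
#' up-regulation, Set1/hypermethylated with down-regulation) and
#' `atypical` otherwise — and (b) the non-DEG remainder, for which
#' per-probe and TRR-median Pearson correlations against expression are
#' computed with BH adjustment, flagging `|r| >= r_min` and
#' `p_adj <= alpha` as significant, together with the whole-TRR
#' consistency flag.
#'
#' @param methyl_sets Tibble from [extract_methyl_sets()].
#' @param manifest Probe manifest tibble.
#' @param methyl M-value matrix.
#' @param degs DEG tibble from [call_degs()].
#' @param counts Count matrix (normalized internally).
#' @param labels Cluster labels ("A"/"B").
#' @param r_min,alpha Significance rule for correlations (defaults 0.7,
#'   0.05).
#' @return A list with `overlap` (tibble: gene, set, direction, label) and
#'   `remainder` (tibble of per-probe correlations with `trr_median_r`,
#'   `whole_trr` per gene).
#' @export
correlate_methyl_sets <- function(methyl_sets, manifest, methyl, degs,
                                  counts, labels, r_min = 0.7,
                                  alpha = 0.05) {
  pairs <- trr_probes(methyl_sets$probe_id, manifest) |>
    dplyr::left_join(methyl_sets[c("probe_id", "set")], by = "probe_id")
  deg_tab <- dplyr::filter(degs, .data$is_deg)
  overlap <- pairs |>
    dplyr::inner_join(deg_tab[c("gene_id", "direction")],
                      by = c(gene = "gene_id")) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      sets = paste(sort(unique(.data$set)), collapse = "+"),
      direction = .data$direction[1],
      label = ifelse(all((.data$set == "Set2" & .data$direction == "up") |
                           (.data$set == "Set1" &
                              .data$direction == "down")),
                     "typical", "atypical"),
      .groups = "drop")

  rem_pairs <- dplyr::anti_join(pairs, deg_tab,
                                by = c(gene = "gene_id")) |>
    dplyr::filter(.data$gene %in% rownames(counts),
                  .data$probe_id %in% rownames(methyl))
  if (nrow(rem_pairs) == 0) {
    return(list(overlap = overlap,
                remainder = tibble(probe_id = character(0),
                                   gene = character(0), set = character(0),
                                   r = numeric(0), p_raw = numeric(0),
                                   p_adj = numeric(0),
                                   significant = logical(0),
                                   trr_median_r = numeric(0),
                                   whole_trr = logical(0))))
  }
  expr <- sweep(counts, 2, size_factors(counts), `/`)
  rp <- row_pearson(methyl[rem_pairs$probe_id, , drop = FALSE],
                    expr[rem_pairs$gene, , drop = FALSE])
  med_r <- vapply(unique(rem_pairs$gene), function(g) {
    med <- gene_trr_median_m(methyl, manifest, g,
                             probes = methyl_sets$probe_id)
    if (sd(med) == 0 || sd(expr[g, ]) == 0) return(NA_real_)
    cor(med, expr[g, ])
  }, numeric(1))
  whole <- vapply(unique(rem_pairs$gene), function(g) {
    as.logical(whole_trr_consistent(g, methyl, labels, manifest))
  }, logical(1))
  remainder <- rem_pairs |>
    dplyr::mutate(r = rp$r, p_raw = rp$p, p_adj = bh_adjust(rp$p),
                  significant = abs(.data$r) >= r_min &
                    .data$p_adj <= alpha,
                  trr_median_r = med_r[.data$gene],
                  whole_trr = whole[.data$gene])
  list(overlap = overlap, remainder = remainder)
}

#' Expression-driven integration and panel distillation (Approach II)
#'
#' Stage 1 correlates every (TRR probe, DEG) pair — the probe's M-values
#' against the gene's size-factor-normalized expression across all samples
#' — with one BH family over all pairs, flags pairs with `|r| >= r_min`
#' and `p_adj <= alpha`, and labels each pair's quadrant (probe
#' methylation status x gene direction, cluster B as reference). Stage 2
#' restricts the pairs to the sign-consistent Methyl-Set probes: the
#' `broad` panel collects DEGs with at least one significant restricted
#' pair, and the `strict` panel keeps the broad genes whose entire TRR is
#' sign-consistent ([whole_trr_consistent()]).
#'
#' @param degs DEG tibble from [call_degs()].
#' @param manifest Probe manifest tibble.
#' @param methyl_sets Tibble from [extract_methyl_sets()].
#' @param methyl M-value matrix.
#' @param counts Count matrix.
#' @param labels Cluster labels ("A"/"B").
#' @param r_min,alpha Correlation significance rule (defaults 0.7, 0.05).
#' @param all_subregions If `TRUE`, stage 1 pairs DEGs with probes in all
#'   sub-regions rather than TRR probes only.
#' @return An object of class `methx_panels`: a list with `records` (one
#'   row per stage-1 pair: r, p, quadrant, `in_methyl_set`), `broad` and
#'   `strict` (gene-level tibbles with direction, supporting probes
#'   list-column, evidence r), and `thresholds`.
#' @export
distill_panels <- function(degs, manifest, methyl_sets, methyl, counts,
                           labels, r_min = 0.7, alpha = 0.05,
                           all_subregions = FALSE) {
  lab <- resolve_labels(labels, colnames(methyl))
  deg_tab <- dplyr::filter(degs, .data$is_deg)
  empty_panel <- tibble(gene = character(0), direction = character(0),
                        n_probes = integer(0), max_abs_r = numeric(0),
                        sets = character(0),
                        probes = list())
  if (nrow(deg_tab) == 0) {
    warn("no differentially expressed genes: panels are empty")
    out <- list(records = tibble(), broad = empty_panel,
                strict = empty_panel,
                thresholds = list(r_min = r_min, alpha = alpha))
    class(out) <- "methx_panels"
    return(out)
  }
  pairs <- manifest |>
    dplyr::filter(.data$gene %in% deg_tab$gene_id)
  if (!all_subregions) {
    pairs <- dplyr::filter(pairs, .data$subregion %in% TRR_SUBREGIONS)
  }
  pairs <- pairs |>
    dplyr::filter(.data$probe_id %in% rownames(methyl)) |>
    dplyr::select("probe_id", "gene", "subregion")
  if (nrow(pairs) == 0) {
    warn("no (TRR probe, DEG) pair available: panels are empty")
    out <- list(records = tibble(), broad = empty_panel,
                strict = empty_panel,
                thresholds = list(r_min = r_min, alpha = alpha))
    class(out) <- "methx_panels"
    return(out)
  }
  expr <- sweep(counts, 2, size_factors(counts), `/`)
  rp <- row_pearson(methyl[pairs$probe_id, , drop = FALSE],
                    expr[pairs$gene, , drop = FALSE])
  med_b <- apply(methyl[pairs$probe_id, lab == "B", drop = FALSE], 1,
                 median)
  records <- pairs |>
    dplyr::left_join(deg_tab[c("gene_id", "direction")],
                     by = c(gene = "gene_id")) |>
    dplyr::mutate(
      r = rp$r, p_raw = rp$p, p_adj = bh_adjust(rp$p),
      significant = !is.na(.data$r) & abs(.data$r) >= r_min &
        .data$p_adj <= alpha,
      status_b = ifelse(med_b < 0, "hypomethylated", "hypermethylated"),
      quadrant = quadrant_label(.data$status_b, .data$direction),
      in_methyl_set = .data$probe_id %in% methyl_sets$probe_id)

  restricted <- dplyr::filter(records, .data$in_methyl_set,
                              .data$significant)
  broad <- restricted |>
    dplyr::left_join(methyl_sets[c("probe_id", "set")], by = "probe_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(direction = .data$direction[1],
                     n_probes = dplyr::n_distinct(.data$probe_id),
                     max_abs_r = max(abs(.data$r)),
                     sets = paste(sort(unique(.data$set)), collapse = "+"),
                     probes = list(unique(.data$probe_id)),
                     .groups = "drop")
  strict_flag <- vapply(broad$gene, function(g) {
    as.logical(whole_trr_consistent(g, methyl, labels, manifest))
  }, logical(1))
  strict <- broad[strict_flag, , drop = FALSE]
  out <- list(records = records, broad = broad, strict = strict,
              thresholds = list(r_min = r_min, alpha = alpha))
  class(out) <- "methx_panels"
  out
}

#' @export
print.methx_panels <- function(x, ...) {
  cat("<methx_panels>\n")
  cat(sprintf("  %d stage-1 pairs, %d significant\n", nrow(x$records),
              sum(x$records$significant %||% logical(0))))
  cat(sprintf("  broad panel: %d genes; strict panel: %d genes\n",
              nrow(x$broad), nrow(x$strict)))
  invisible(x)
}

#' Quadrant tallies of significant probe-gene pairs
#'
#' Counts significant correlation records per methylation-expression
#' quadrant (cluster B as reference) and the derived negative-direction
#' (Hypo_Up + Hyper_Down) and positive-direction (Hypo_Down + Hyper_Up)
#' totals; the four quadrants always sum to the significant-pair count.
#'
#' @param records Stage-1 record tibble from [distill_panels()] (or any
#'   tibble with `significant` and `quadrant`).
#' @return A list with `by_quadrant` (tibble `quadrant`, `n`), `negative`,
#'   `positive` and `significant`.
#' @export
quadrant_counts <- function(records) {
  lev <- c("Hyper_Down", "Hyper_Up", "Hypo_Down", "Hypo_Up")
  if (nrow(records) == 0) {
    tab <- tibble(quadrant = lev, n = 0L)
  } else {
    sig <- dplyr::filter(records, .data$significant)
    tab <- tibble(quadrant = lev) |>
      dplyr::left_join(dplyr::count(sig, .data$quadrant), by = "quadrant") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  n_of <- function(q) tab$n[tab$quadrant == q]
  list(by_quadrant = tab,
       negative = n_of("Hypo_Up") + n_of("Hyper_Down"),
       positive = n_of("Hypo_Down") + n_of("Hyper_Up"),
       significant = sum(tab$n))
}

#' Re-cluster samples on a distilled gene panel
#'
#' Repeats the two-cluster discovery using only (a) the panel's supporting
#' probes' M-values and (b) the panel genes' variance-stabilized
#' expression, and reports the concordance (adjusted Rand index and exact
#' match) of each against a reference clustering.
#'
#' @param panel A panel tibble (`broad` or `strict` from
#'   [distill_panels()]), with `gene` and a `probes` list-column.
#' @param methyl M-value matrix.
#' @param counts Count matrix.
#' @param reference Reference `methx_clustering`.
#' @return A list with elements `methylation` and `expression`, each
#'   holding `ari`, `exact_match` and the `clustering`.
#' @export
panel_reclustering <- function(panel, methyl, counts, reference) {
  if (nrow(panel) == 0) abort("panel is empty")
  probes <- intersect(unique(unlist(panel$probes)), rownames(methyl))
  genes <- intersect(panel$gene, rownames(counts))
  if (length(probes) < 2 || length(genes) < 2) {
    abort("panel must contribute at least 2 probes and 2 genes")
  }
  cl_m <- assign_two_clusters(methyl[probes, , drop = FALSE])
  cl_e <- assign_two_clusters(vst_counts(counts)[genes, , drop = FALSE])
  cm <- cluster_concordance(cl_m, reference)
  ce <- cluster_concordance(cl_e, reference)
  list(
    methylation = list(ari = cm$ari, exact_match = cm$exact_match,
                       clustering = cl_m),
    expression = list(ari = ce$ari, exact_match = ce$exact_match,
                      clustering = cl_e))
}
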