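# per-probe sign pattern against the strict Methyl-Set criteria:
# "Set1"  all cluster-A values < 0 < all cluster-B values
# "Set2"  all cluster-A values > 0 > all cluster-B values
# NA      neither (includes any value exactly 0)
probe_sign_pattern <- function(m, in_a) {
  max_a <- apply(m[, in_a, drop = FALSE], 1, max)
  min_a <- apply(m[, in_a, drop = FALSE], 1, min)
  max_b <- apply(m[, !in_a, drop = FALSE], 1, max)
  min_b <- apply(m[, !in_a, drop = FALSE], 1, min)
  dplyr::case_when(
    max_a < 0 & min_b > 0 ~ "Set1",
    min_a > 0 & max_b < 0 ~ "Set2",
    TRUE ~ NA_character_)
}

#' Categorize DMPs by CGI relation and gene sub-region
#'
#' Cross-tabulates differentially methylated probes against their CpG-
#' island relation (counted once per probe) and gene sub-region (counted
#' once per (probe, gene) pair), split by the per-cluster methylation
#' status from [call_dmps()]. Probes absent from the manifest fall into an
#' "intergenic" bucket. The wide tables feed
#' [chi_square_association()] directly.
#'
#' @param dmps DMP tibble from [call_dmps()] (only `is_dmp` rows are used).
#' @param manifest Probe manifest tibble.
#' @return A list with tibbles `cgi` and `subregion`, each with columns
#'   `category`, `hypo_A`, `hyper_A`, `hypo_B`, `hyper_B`, `n` and `frac`
#'   (fractions sum to 1 per table).
#' @export
categorize_dmps <- function(dmps, manifest) {
  sig <- dplyr::filter(dmps, .data$is_dmp)
  status_cols <- function(df, category) {
    out <- df |>
      dplyr::group_by(category = {{ category }}) |>
      dplyr::summarise(
        hypo_A = sum(.data$status_a == "hypomethylated"),
        hyper_A = sum(.data$status_a == "hypermethylated"),
        hypo_B = sum(.data$status_b == "hypomethylated"),
        hyper_B = sum(.data$status_b == "hypermethylated"),
        n = dplyr::n(), .groups = "drop")
    out$frac <- out$n / sum(out$n)
    out
  }
  probe_cgi <- manifest |>
    dplyr::distinct(.data$probe_id, .data$cgi_relation)
  cgi <- sig |>
    dplyr::left_join(probe_cgi, by = "probe_id") |>
    dplyr::mutate(cgi_relation = dplyr::coalesce(.data$cgi_relation,
                                                 "intergenic"))
  sub <- sig |>
    dplyr::left_join(manifest[c("probe_id", "gene", "subregion")],
                     by = "probe_id", relationship = "many-to-many") |>
    dplyr::mutate(subregion = dplyr::coalesce(.data$subregion,
                                              "intergenic"))
  list(cgi = status_cols(cgi, .data$cgi_relation),
       subregion = status_cols(sub, .data$subregion))
}

#' Extract the sign-consistent Methyl-Sets
#'
#' From the DMPs, selects Set1 probes (every cluster-A M-value strictly
#' negative and every cluster-B M-value strictly positive) and Set2 probes
#' (the mirror image). All inequalities are strict over raw per-sample
#' M-values; a value of exactly zero disqualifies the probe. Probes
#' satisfying neither criterion — the "same methylation state" majority —
#' are excluded.
#'
#' @param dmps DMP tibble from [call_dmps()].
#' @param methyl M-value matrix.
#' @param labels Cluster labels ("A"/"B").
#' @return A tibble with `probe_id`, `set` ("Set1"/"Set2") and per-cluster
#'   extrema `max_m_a`, `min_m_a`, `max_m_b`, `min_m_b`.
#' @export
extract_methyl_sets <- function(dmps, methyl, labels) {
  check_feature_matrix(methyl, "methylation matrix")
  lab <- resolve_labels(labels, colnames(methyl))
  sig_probes <- dmps$probe_id[dmps$is_dmp]
  if (length(sig_probes) == 0) {
    return(tibble(probe_id = character(0), set = character(0),
                  max_m_a = numeric(0), min_m_a = numeric(0),
                  max_m_b = numeric(0), min_m_b = numeric(0)))
  }
  m <- methyl[sig_probes, , drop = FALSE]
  in_a <- lab == "A"
  pattern <- probe_sign_pattern(m, in_a)
  keep <- !is.na(pattern)
  tibble(
    probe_id = sig_probes[keep], set = pattern[keep],
    max_m_a = apply(m[keep, in_a, drop = FALSE], 1, max),
    min_m_a = apply(m[keep, in_a, drop = FALSE], 1, min),
    max_m_b = apply(m[keep, !in_a, drop = FALSE], 1, max),
    min_m_b = apply(m[keep, !in_a, drop = FALSE], 1, min))
}

#' Transcriptional-regulatory-region probes of a probe set
#'
#' Restricts a probe set to its (probe, gene) pairs annotated in the TRR
#' sub-regions TSS1500, TSS200, 5'UTR or 1stExon, and summarises the
#' sub-region composition.
#'
#' @param probe_ids Character vector of probe ids.
#' @param manifest Probe manifest tibble.
#' @return A tibble with `probe_id`, `gene`, `subregion`, carrying a
#'   `summary` attribute (tibble of per-sub-region pair counts and
#'   fractions summing to 1).
#' @export
trr_probes <- function(probe_ids, manifest) {
  out <- manifest |>
    dplyr::filter(.data$probe_id %in% probe_ids,
                  .data$subregion %in% TRR_SUBREGIONS) |>
    dplyr::select("probe_id", "gene", "subregion")
  summ <- out |>
    dplyr::count(.data$subregion, name = "n_pairs") |>
    dplyr::mutate(frac = .data$n_pairs / sum(.data$n_pairs))
  attr(out, "summary") <- summ
  out
}

#' Per-sample TRR median methylation of a gene
#'
#' For one gene, the per-sample median M-value over its TRR probes
#' (optionally restricted to a probe filter). With a single probe this is
#' that probe's values.
#'
#' @param methyl M-value matrix.
#' @param manifest Probe manifest tibble.
#' @param gene Gene symbol.
#' @param probes Optional probe-id filter applied before aggregation.
#' @return Named numeric vector, one median per sample.
#' @export
gene_trr_median_m <- function(methyl, manifest, gene, probes = NULL) {
  ids <- manifest$probe_id[manifest$gene == gene &
                             manifest$subregion %in% TRR_SUBREGIONS]
  if (!is.null(probes)) ids <- intersect(ids, probes)
  ids <- intersect(unique(ids), rownames(methyl))
  if (length(ids) == 0) {
    abort(paste0("gene ", gene, " has no TRR probe passing the filter"))
  }
  apply(methyl[ids, , drop = FALSE], 2, median)
}

#' Whole-TRR sign consistency of a gene
#'
#' `TRUE` when every TRR probe of the gene individually satisfies the same
#' strict Methyl-Set sign criterion (all Set1-pattern, or all
#' Set2-pattern). This is the probe-wise reading of "replicating the
#' methylation state of the entire TRR"; the weaker TRR-median-sign rule is
#' available via `rule = "median"`.
#'
#' @param gene Gene symbol (must have at least one TRR probe).
#' @param methyl M-value matrix.
#' @param labels Cluster labels ("A"/"B").
#' @param manifest Probe manifest tibble.
#' @param rule `"probewise"` (default) or `"median"`.
#' @return Logical flag with attribute `pattern` ("Set1", "Set2" or `NA`).
#' @export
whole_trr_consistent <- function(gene, methyl, labels, manifest,
                                 rule = c("probewise", "median")) {
  rule <- match.arg(rule)
  lab <- resolve_labels(labels, colnames(methyl))
  in_a <- lab == "A"
  ids <- unique(manifest$probe_id[manifest$gene == gene &
                                    manifest$subregion %in% TRR_SUBREGIONS])
  ids <- intersect(ids, rownames(methyl))
  if (length(ids) == 0) {
    abort(paste0("gene ", gene, " has no TRR probe"))
  }
  if (rule == "median") {
    med <- gene_trr_median_m(methyl, manifest, gene)
    pattern <- probe_sign_pattern(matrix(med, nrow = 1,
                                         dimnames = list("med",
                                                         names(med))),
                                  in_a)
  } else {
    pats <- probe_sign_pattern(methyl[ids, , drop = FALSE], in_a)
    pattern <- if (!anyNA(pats) && length(unique(pats)) == 1) {
      pats[1]
    } else {
      NA_character_
    }
  }
  structure(!is.na(pattern), pattern = pattern)
}
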