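#' Read a features-by-samples matrix from TSV
#'
#' Reads a tab-separated matrix whose header row holds sample ids and whose
#' first column holds feature ids, validating it according to its kind:
#' `"methylation"` (finite M-values), `"detection_p"` (values in `[0, 1]`)
#' or `"counts"` (non-negative integers; fractional values are a parse
#' error).
#'
#' @param path Path to a TSV file.
#' @param kind One of `"methylation"`, `"detection_p"`, `"counts"`.
#' @return A numeric matrix (integer storage for counts) with feature
#'   rownames and sample colnames.
#' @export
read_omics_matrix <- function(path,
                              kind = c("methylation", "detection_p",
                                       "counts")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("matrix file needs a feature column and at least one sample column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate feature id: ", ids[duplicated(ids)][1]))
  }
  mat_df <- df[-1]
  bad_col <- which(!vapply(mat_df, is.numeric, logical(1)))
  if (length(bad_col) > 0) {
    abort(paste0("non-numeric cells in column `", names(mat_df)[bad_col[1]],
                 "`"))
  }
  x <- as.matrix(mat_df)
  rownames(x) <- ids
  if (anyDuplicated(colnames(x))) abort("duplicate sample ids in header")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite value at row %s, column %s",
                  rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (kind == "counts") {
    if (any(x < 0) || any(x != round(x))) {
      bad <- which(x < 0 | x != round(x), arr.ind = TRUE)[1, ]
      abort(sprintf("counts must be non-negative integers; offending cell at row %s, column %s",
                    rownames(x)[bad[1]], colnames(x)[bad[2]]))
    }
    storage.mode(x) <- "integer"
  }
  if (kind == "detection_p" && (any(x < 0) || any(x > 1))) {
    abort("detection P-values must lie in [0, 1]")
  }
  x
}

#' Write a features-by-samples matrix to TSV
#'
#' Inverse of [read_omics_matrix()]: header row of sample ids, first column
#' `feature_id`. Numbers are written at full precision so the round trip is
#' lossless.
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_omics_matrix <- function(x, path) {
  check_feature_matrix(x)
  df <- tibble::as_tibble(x, rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

validate_manifest <- function(manifest) {
  req <- c("probe_id", "chrom", "pos", "gene", "subregion", "cgi_relation")
  missing <- setdiff(req, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_sub <- setdiff(unique(manifest$subregion), SUBREGIONS)
  if (length(bad_sub) > 0) {
    abort(paste0("unknown gene sub-region token(s): ",
                 paste(bad_sub, collapse = ", ")))
  }
  bad_cgi <- setdiff(unique(manifest$cgi_relation), CGI_RELATIONS)
  if (length(bad_cgi) > 0) {
    abort(paste0("unknown CGI relation token(s): ",
                 paste(bad_cgi, collapse = ", ")))
  }
  if (anyDuplicated(manifest[c("probe_id", "gene")])) {
    abort("duplicated (probe_id, gene) pair in manifest")
  }
  tibble::as_tibble(manifest)
}

#' Read and validate a probe manifest
#'
#' Reads a CSV probe annotation with columns `probe_id`, `chrom`, `pos`,
#' `gene`, `subregion`, `cgi_relation`. Multi-gene probes may appear either
#' as one row per (probe, gene) pair or packed with `;`-separated `gene`
#' and `subregion` fields; packed rows are expanded. Sub-region and
#' CGI-relation vocabularies are closed; unknown tokens are a validation
#' error.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with one row per (probe, gene) pair.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("probe_id", "chrom", "pos", "gene", "subregion", "cgi_relation")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  packed <- grepl(";", df$gene, fixed = TRUE)
  if (any(packed)) {
    expanded <- purrr::pmap_dfr(df[packed, ], function(probe_id, chrom, pos,
                                                       gene, subregion,
                                                       cgi_relation, ...) {
      genes <- strsplit(gene, ";", fixed = TRUE)[[1]]
      subs <- strsplit(subregion, ";", fixed = TRUE)[[1]]
      if (length(subs) == 1) subs <- rep(subs, length(genes))
      if (length(subs) != length(genes)) {
        abort(paste0("probe ", probe_id,
                     ": gene and subregion lists differ in length"))
      }
      tibble(probe_id = probe_id, chrom = chrom, pos = pos, gene = genes,
             subregion = subs, cgi_relation = cgi_relation)
    })
    df <- dplyr::bind_rows(df[!packed, req], expanded)
  } else {
    df <- df[req]
  }
  validate_manifest(dplyr::arrange(df, .data$probe_id, .data$gene))
}

#' Read a sample table
#'
#' Reads a TSV sample table with at least `sample_id`; recognised optional
#' columns include a cluster label, `pfs_months` (non-negative) and `event`
#' (0/1), plus free clinical covariates.
#'
#' @param path Path to the sample TSV.
#' @return A tibble.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) abort("sample table needs a `sample_id` column")
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id in sample table")
  if ("pfs_months" %in% names(df) &&
      any(df$pfs_months < 0, na.rm = TRUE)) {
    abort("`pfs_months` must be non-negative")
  }
  if ("event" %in% names(df) &&
      !all(df$event %in% c(0L, 1L) | is.na(df$event))) {
    abort("`event` must be 0 or 1")
  }
  tibble::as_tibble(df)
}

#' Align methylation, expression and sample table on shared samples
#'
#' Restricts the three inputs to their common sample set in one canonical
#' (sorted) order. Samples present in some inputs but not all are dropped
#' with a warning.
#'
#' @param methyl M-value matrix (probes x samples).
#' @param counts Count matrix (genes x samples).
#' @param samples Sample table with `sample_id`.
#' @return A list with the three aligned components.
#' @export
align_samples <- function(methyl, counts, samples) {
  check_feature_matrix(methyl, "methylation matrix")
  check_feature_matrix(counts, "count matrix")
  if (!"sample_id" %in% names(samples)) {
    abort("sample table needs a `sample_id` column")
  }
  common <- sort(Reduce(intersect, list(colnames(methyl), colnames(counts),
                                        samples$sample_id)))
  if (length(common) == 0) abort("no sample shared across the three inputs")
  dropped <- setdiff(unique(c(colnames(methyl), colnames(counts),
                              samples$sample_id)), common)
  if (length(dropped) > 0) {
    warn(paste0("dropping sample(s) absent from some inputs: ",
                paste(dropped, collapse = ", ")))
  }
  list(
    methyl = methyl[, common, drop = FALSE],
    counts = counts[, common, drop = FALSE],
    samples = samples[match(common, samples$sample_id), , drop = FALSE])
}
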