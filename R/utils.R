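# internal helpers shared across modules

# Named sub-stream seeds derived from one global seed, so each simulation
# component is reproducible on its own. Result stays below 2^31.
sub_seed <- function(seed, stream) {
  offsets <- c(manifest = 101L, methylation = 211L, expression = 307L,
               survival = 401L)
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown seed stream: ", stream))
  }
  as.integer((as.double(seed) %% 1e9) * 2 + offsets[[stream]]) %% 2147483647L
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single fraction in [0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(x)
}

# Closed vocabularies used throughout
SUBREGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "ExonBnd",
                "3'UTR")
TRR_SUBREGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
CGI_RELATIONS <- c("Island", "Shore-N", "Shore-S", "Shelf-N", "Shelf-S",
                   "OpenSea")
SEX_CHROMS <- c("chrX", "X", "chrY", "Y")

# Resolve a cluster labelling argument into a named character vector of
# "A"/"B" per sample. Accepts a methx_clustering tibble, a two-column
# data frame (sample_id, cluster) or a named vector.
resolve_labels <- function(labels, sample_ids = NULL) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "cluster") %in% names(labels))) {
      abort("label data frame needs `sample_id` and `cluster` columns")
    }
    out <- setNames(as.character(labels$cluster), labels$sample_id)
  } else if (!is.null(names(labels))) {
    out <- setNames(as.character(labels), names(labels))
  } else {
    abort("cluster labels must be a data frame or a named vector")
  }
  if (!all(out %in% c("A", "B"))) {
    abort("cluster labels must be 'A' or 'B'")
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(out))
    if (length(missing) > 0) {
      abort(paste0("no cluster label for sample(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    out <- out[sample_ids]
  }
  out
}

check_feature_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(paste0(what, " must be a numeric matrix (features x samples)"))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(paste0(what, " must have feature rownames and sample colnames"))
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort(paste0(what, " has duplicated feature or sample ids"))
  }
  if (any(!is.finite(x))) {
    abort(paste0(what, " contains non-finite values"))
  }
  invisible(x)
}
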