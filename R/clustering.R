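#' Euclidean distance between samples
#'
#' Pairwise Euclidean distances between the columns (samples) of a
#' features-by-samples matrix.
#'
#' @param x Numeric matrix, features x samples, complete and finite.
#' @return Symmetric non-negative matrix of sample-sample distances with
#'   zero diagonal.
#' @export
distance_matrix <- function(x) {
  check_feature_matrix(x)
  as.matrix(dist(t(x), method = "euclidean"))
}

new_embedding <- function(coordinates, eigenvalues, method) {
  structure(list(coordinates = coordinates, eigenvalues = eigenvalues,
                 method = method),
            class = "methx_embedding")
}

#' @export
print.methx_embedding <- function(x, ...) {
  cat(sprintf("<methx_embedding> %s: %d samples x %d components\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix (B = -1/2 J D^2 J), takes the
#' top-k eigenpairs and scales eigenvectors by the square root of their
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are truncated to
#' zero with a warning; if fewer than `k` positive dimensions exist, `k` is
#' reduced with a warning.
#'
#' @param d Symmetric distance matrix (e.g. [distance_matrix()]).
#' @param k Number of output dimensions.
#' @return A `methx_embedding` with `coordinates` (samples x k),
#'   `eigenvalues` (non-increasing) and `method = "MDS"`.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(!is.finite(d))) {
    abort("`d` must be a finite symmetric distance matrix")
  }
  if (k < 1) abort("`k` must be at least 1")
  n <- nrow(d)
  k_req <- min(k, n - 1L)
  fit <- suppressWarnings(cmdscale(as.dist(d), k = k_req, eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warn("negative eigenvalues truncated to zero (non-Euclidean distances)")
  }
  coords <- fit$points
  if (ncol(coords) < k) {
    warn(sprintf("rank supports only %d of %d requested dimensions; padding with zeros",
                 ncol(coords), k))
    pad <- matrix(0, n, k - ncol(coords))
    coords <- cbind(coords, pad)
  }
  colnames(coords) <- paste0("Dim", seq_len(ncol(coords)))
  rownames(coords) <- rownames(d)
  new_embedding(coords[, seq_len(k), drop = FALSE],
                pmax(head(sort(eig, decreasing = TRUE), k), 0), "MDS")
}

#' Principal component analysis of samples
#'
#' Feature-wise centering followed by singular value decomposition; sample
#' scores have diagonal covariance. A constant input matrix yields all-zero
#' scores with a warning.
#'
#' @param x Numeric matrix, features x samples (at least two samples).
#' @param k Number of components.
#' @return A `methx_embedding` with `coordinates` (sample scores),
#'   `eigenvalues` (component variances) and `method = "PCA"`.
#' @export
pca_embedding <- function(x, k = 2) {
  check_feature_matrix(x)
  if (ncol(x) < 2) abort("PCA needs at least 2 samples")
  k <- min(k, ncol(x) - 1L)
  if (all(apply(x, 1, function(r) diff(range(r))) == 0)) {
    warn("constant matrix: PCA scores are all zero")
    coords <- matrix(0, ncol(x), k,
                     dimnames = list(colnames(x), paste0("PC", seq_len(k))))
    return(new_embedding(coords, rep(0, k), "PCA"))
  }
  fit <- prcomp(t(x), center = TRUE, scale. = FALSE)
  kk <- min(k, ncol(fit$x))
  coords <- fit$x[, seq_len(kk), drop = FALSE]
  if (kk < k) {
    coords <- cbind(coords, matrix(0, nrow(coords), k - kk))
    colnames(coords) <- paste0("PC", seq_len(k))
  }
  new_embedding(coords, c(fit$sdev^2, rep(0, k))[seq_len(k)], "PCA")
}

mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- mean(d[i, !(labels == labels[i])])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Deterministic two-group assignment
#'
#' Cuts a Ward-linkage (ward.D2) agglomerative tree over Euclidean
#' distances on the top-2 embedding coordinates into two groups. The larger
#' cluster is labelled "A" (ties broken by the cluster containing the
#' lexicographically smallest sample id). No randomness is involved. The
#' mean silhouette width of the 2-D solution is attached; values below 0.25
#' are flagged low-confidence.
#'
#' @param x A `methx_embedding`, or a features-by-samples matrix (embedded
#'   internally via classical MDS unless `full_matrix = TRUE`, in which
#'   case clustering runs on the full feature space).
#' @param components Number of leading embedding coordinates used
#'   (default 2).
#' @param full_matrix If `TRUE` and `x` is a matrix, cluster on all
#'   features instead of the 2-D embedding.
#' @return A tibble of class `methx_clustering` with `sample_id` and
#'   `cluster`, and attributes `silhouette`, `low_confidence` and
#'   `linkage`.
#' @export
assign_two_clusters <- function(x, components = 2, full_matrix = FALSE) {
  if (inherits(x, "methx_embedding")) {
    coords <- x$coordinates[, seq_len(min(components, ncol(x$coordinates))),
                            drop = FALSE]
    sil_space <- coords
  } else {
    check_feature_matrix(x)
    if (full_matrix) {
      coords <- t(x)
    } else {
      emb <- classical_mds(distance_matrix(x), k = components)
      coords <- emb$coordinates
    }
    # confidence is judged in the full feature space, not the 2-D view
    sil_space <- t(x)
  }
  if (nrow(coords) < 4) abort("need at least 4 samples to cluster")
  hc <- hclust(dist(coords), method = "ward.D2")
  grp <- cutree(hc, k = 2)
  ids <- rownames(coords)
  n1 <- sum(grp == 1); n2 <- sum(grp == 2)
  a_group <- if (n1 > n2) 1L else if (n2 > n1) 2L else {
    grp[[which.min(ids)]]
  }
  labels <- unname(ifelse(grp == a_group, "A", "B"))
  sil <- mean_silhouette(sil_space, labels)
  out <- tibble(sample_id = ids, cluster = labels)
  class(out) <- c("methx_clustering", class(out))
  attr(out, "silhouette") <- sil
  attr(out, "low_confidence") <- sil < 0.25
  attr(out, "linkage") <- "ward.D2"
  out
}

#' Concordance between two clusterings
#'
#' Adjusted Rand index plus an exact-match flag (identical partitions up to
#' label swap) for two clusterings of the same sample set.
#'
#' @param c1,c2 `methx_clustering` tibbles (or data frames with
#'   `sample_id`, `cluster`).
#' @return A list with `ari` and `exact_match`.
#' @export
cluster_concordance <- function(c1, c2) {
  l1 <- resolve_labels(c1)
  l2 <- resolve_labels(c2)
  if (!setequal(names(l1), names(l2))) {
    abort("clusterings cover different sample sets")
  }
  l2 <- l2[names(l1)]
  ari <- mclust::adjustedRandIndex(l1, l2)
  exact <- identical(unname(l1), unname(l2)) ||
    identical(unname(l1), unname(ifelse(l2 == "A", "B", "A")))
  list(ari = ari, exact_match = exact)
}
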