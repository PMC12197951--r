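#' Plot an ordination embedding
#'
#' Scatter plot of the first two embedding coordinates, optionally colored
#' by cluster labels.
#'
#' @param object A `methx_embedding`.
#' @param labels Optional cluster labels ("A"/"B").
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methx_embedding
#' @export
autoplot.methx_embedding <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object$coordinates[, 1:2, drop = FALSE],
                          rownames = "sample_id")
  names(df)[2:3] <- c("dim1", "dim2")
  if (!is.null(labels)) {
    lab <- resolve_labels(labels, df$sample_id)
    df$cluster <- lab
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          color = .data$cluster,
                                          shape = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = paste(object$method, "1"),
                  y = paste(object$method, "2")) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression
#'
#' log2 fold-change against -log10 adjusted p, with the DEG thresholds
#' drawn and flagged genes highlighted.
#'
#' @param degs Tibble from [call_degs()].
#' @param alpha,lfc_min Thresholds to draw (defaults 0.01, 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(degs, alpha = 0.01, lfc_min = 2) {
  df <- dplyr::filter(degs, .data$tested)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc,
                                   -log10(pmax(.data$p_adj, 1e-300)),
                                   color = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change (B vs A)",
                  y = "-log10 adjusted p", color = "DEG") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A `methx_km`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methx_km
#' @export
autoplot.methx_km <- function(object, ...) {
  df <- dplyr::bind_rows(tibble(time = 0, surv = 1), object$curve)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Progression-free survival") +
    ggplot2::theme_minimal()
}

#' Quadrant composition of significant probe-gene pairs
#'
#' Bar chart of significant correlation pairs per methylation-expression
#' quadrant (cluster B as reference).
#'
#' @param records Stage-1 records from [distill_panels()].
#' @return A ggplot object.
#' @export
plot_quadrants <- function(records) {
  qc <- quadrant_counts(records)
  ggplot2::ggplot(qc$by_quadrant,
                  ggplot2::aes(.data$quadrant, .data$n,
                               fill = .data$quadrant)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Significant probe-gene pairs") +
    ggplot2::theme_minimal()
}
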