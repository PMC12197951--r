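#' Tidy a clustering result
#'
#' @param x A `methx_clustering`.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `cluster`.
#' @method tidy methx_clustering
#' @export
tidy.methx_clustering <- function(x, ...) {
  tibble(sample_id = x$sample_id, cluster = x$cluster)
}

#' One-row summary of a clustering result
#'
#' @param x A `methx_clustering`.
#' @param ... Unused.
#' @return A tibble with cluster sizes, silhouette and confidence flag.
#' @method glance methx_clustering
#' @export
glance.methx_clustering <- function(x, ...) {
  tibble(n_a = sum(x$cluster == "A"), n_b = sum(x$cluster == "B"),
         silhouette = attr(x, "silhouette"),
         low_confidence = attr(x, "low_confidence"))
}

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `methx_km` from [km_estimate()].
#' @param ... Unused.
#' @return The step-function tibble (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`).
#' @method tidy methx_km
#' @export
tidy.methx_km <- function(x, ...) x$curve

#' One-row summary of a Kaplan-Meier curve
#'
#' @param x A `methx_km`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `median`.
#' @method glance methx_km
#' @export
glance.methx_km <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median = x$median)
}

#' Tidy the panel distillation result
#'
#' @param x A `methx_panels` from [distill_panels()].
#' @param ... Unused.
#' @return The stage-1 correlation record tibble.
#' @method tidy methx_panels
#' @export
tidy.methx_panels <- function(x, ...) x$records

#' One-row summary of the panel distillation
#'
#' @param x A `methx_panels`.
#' @param ... Unused.
#' @return A tibble with pair and panel counts.
#' @method glance methx_panels
#' @export
glance.methx_panels <- function(x, ...) {
  sig <- if (nrow(x$records) > 0) sum(x$records$significant) else 0L
  tibble(n_pairs = nrow(x$records), n_significant = sig,
         broad_panel = nrow(x$broad), strict_panel = nrow(x$strict))
}

#' Tidy a pipeline report into a long metric table
#'
#' @param x A `methx_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with `metric` and `value` columns.
#' @method tidy methx_report
#' @export
tidy.methx_report <- function(x, ...) {
  tibble(metric = names(x$counts),
         value = vapply(x$counts, function(v) {
           if (is.logical(v)) as.numeric(v) else as.numeric(v)
         }, numeric(1)))
}

#' One-row summary of a pipeline report
#'
#' @param x A `methx_report`.
#' @param ... Unused.
#' @return A one-row tibble of all scalar report metrics.
#' @method glance methx_report
#' @export
glance.methx_report <- function(x, ...) {
  tibble::as_tibble(x$counts)
}
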