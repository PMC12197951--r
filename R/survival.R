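#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function. Censored subjects at a
#' time t remain at risk for events at t (events processed before
#' censorings at ties). The median is the first time the curve drops to
#' 0.5 or below, and is reported as `NA` when the curve never does —
#' deliberately not infinity, to keep small-cohort reporting honest.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return An object of class `methx_km`: a list with `curve` (tibble:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`) and `median`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("empty survival input")
  if (any(times < 0)) abort("times must be non-negative")
  if (!all(events %in% c(0, 1))) abort("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  curve <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  surv = fit$surv)
  med <- unname(summary(fit)$table["median"])
  structure(list(curve = curve, median = med, n = length(times),
                 n_events = sum(events)),
            class = "methx_km")
}

#' @export
print.methx_km <- function(x, ...) {
  cat(sprintf("<methx_km> n = %d, events = %d, median = %s\n", x$n,
              x$n_events,
              ifelse(is.na(x$median), "not reached",
                     format(x$median, digits = 4))))
  invisible(x)
}

#' Log-rank comparison of two survival curves
#'
#' Standard observed-minus-expected chi-square over the shared event-time
#' grid, one degree of freedom. Invariant to relabelling the groups;
#' identical groups give statistic 0, p = 1.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Two-level group labels, each level non-empty.
#' @return A list with `statistic`, `df` and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    abort("log-rank comparison needs exactly two non-empty groups")
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  list(statistic = fit$chisq, df = df,
       p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Ellipsoid-style tumor volume
#'
#' `width x height x length x 0.5`, in cubic centimeters.
#'
#' @param width_cm,height_cm,length_cm Lesion dimensions in cm, all
#'   positive.
#' @return Volume in cm^3.
#' @export
#' @examples
#' tumor_volume(3.4, 2.0, 2.9)  # 9.86
tumor_volume <- function(width_cm, height_cm, length_cm) {
  if (any(c(width_cm, height_cm, length_cm) <= 0)) {
    abort("all lesion dimensions must be positive")
  }
  width_cm * height_cm * length_cm * 0.5
}

#' Cluster-wise progression-free-survival comparison
#'
#' Kaplan-Meier curves per cluster plus the log-rank test between them.
#'
#' @param samples Sample table with `sample_id`, `pfs_months`, `event`.
#' @param labels Cluster labels ("A"/"B").
#' @return A list with `km_a`, `km_b` ([km_estimate()] objects),
#'   `median_a`, `median_b` and `logrank` (list: statistic, df, p).
#' @export
compare_pfs <- function(samples, labels) {
  lab <- resolve_labels(labels, samples$sample_id)
  in_a <- lab == "A"
  km_a <- km_estimate(samples$pfs_months[in_a], samples$event[in_a])
  km_b <- km_estimate(samples$pfs_months[!in_a], samples$event[!in_a])
  lr <- logrank_test(samples$pfs_months, samples$event, lab)
  list(km_a = km_a, km_b = km_b, median_a = km_a$median,
       median_b = km_b$median, logrank = lr)
}
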