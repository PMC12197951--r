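# shared fixture builders: small, fast cohorts with known ground truth

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_probes = 800, n_genes = 200, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

truth_labels <- function(cohort) {
  tibble::tibble(sample_id = cohort$truth$samples$sample_id,
                 cluster = cohort$truth$samples$cluster_truth)
}

# precision/recall of a predicted id set against a truth id set
set_pr <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  list(recall = if (length(truth) == 0) NA_real_ else tp / length(truth),
       precision = if (length(predicted) == 0) NA_real_
                   else tp / length(predicted))
}
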