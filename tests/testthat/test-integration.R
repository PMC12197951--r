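test_that("Pearson r and p match the direct-formula oracle", {
  res <- pearson_with_p(c(1, 2, 3), c(6, 4, 2))
  expect_equal(res$r, -1)
  expect_equal(res$p, 0)

  # orthogonal after centering: r = 0, p = 1
  res0 <- pearson_with_p(c(1, 2, 3), c(1, -2, 1))
  expect_equal(res0$r, 0)
  expect_equal(res0$p, 1)

  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    res <- pearson_with_p(x, y)
    # independent evaluation of the textbook formulae
    n <- 15
    r_o <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_o <- r_o * sqrt((n - 2) / (1 - r_o^2))
    p_o <- 2 * pt(-abs(t_o), n - 2)
    expect_equal(res$r, r_o, tolerance = 1e-10)
    expect_equal(res$p, p_o, tolerance = 1e-10)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("methylation-driven integration labels overlap genes by sign logic", {
  # hand-built case: two Set-pattern probes, one typical and one atypical gene
  m <- matrix(c(-2, -1, -2, 1, 2, 1.5,   # cg1: Set1 (hyper in B)
                2, 1, 1.5, -1, -2, -1),  # cg2: Set2 (hypo in B)
              2, 6, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), sprintf("S%02d", 1:6)))
  labels <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  manifest <- tibble::tibble(
    probe_id = c("cg1", "cg2"), chrom = "chr1", pos = 1:2,
    gene = c("GDOWN", "GUPX"), subregion = "TSS200",
    cgi_relation = "Island")
  sets <- tibble::tibble(probe_id = c("cg1", "cg2"),
                         set = c("Set1", "Set2"))
  degs <- tibble::tibble(gene_id = c("GDOWN", "GUPX"),
                         is_deg = TRUE, direction = c("down", "up"))
  counts <- matrix(10L, 2, 6, dimnames = list(c("GDOWN", "GUPX"),
                                              colnames(m)))
  res <- correlate_methyl_sets(sets, manifest, m, degs, counts, labels)
  expect_equal(res$overlap$label[res$overlap$gene == "GDOWN"], "typical")
  expect_equal(res$overlap$label[res$overlap$gene == "GUPX"], "typical")

  # flip GDOWN to up-regulated: Set1 + up is the atypical pattern
  degs2 <- dplyr::mutate(degs, direction = c("up", "up"))
  res2 <- correlate_methyl_sets(sets, manifest, m, degs2, counts, labels)
  expect_equal(res2$overlap$label[res2$overlap$gene == "GDOWN"],
               "atypical")
})

test_that("non-DEG Methyl-Set genes with coupling are recovered as correlated", {
  co <- simulate_cohort(tiny_config(seed = 32))
  lab <- truth_labels(co)
  dmps <- call_dmps(co$m, lab)
  sets <- extract_methyl_sets(dmps, co$m, lab)
  # pretend the planted panel genes were not DEGs so they land in the
  # correlation remainder of the methylation-driven branch
  degs_none <- call_degs(co$counts, lab)
  degs_none$is_deg <- FALSE
  res <- correlate_methyl_sets(sets, co$manifest, co$m, degs_none,
                               co$counts, lab)
  panel <- co$truth$genes$gene_id[co$truth$genes$panel_flag]
  rec <- res$remainder |>
    dplyr::filter(.data$gene %in% panel) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(hit = any(.data$significant))
  expect_gte(mean(rec$hit), 0.9)
  expect_true(all(res$remainder$trr_median_r[
    res$remainder$gene %in% panel] < 0))
})

test_that("panel distillation recovers planted broad and strict panels", {
  co <- simulate_cohort(tiny_config(seed = 33))
  lab <- truth_labels(co)
  dmps <- call_dmps(co$m, lab)
  sets <- extract_methyl_sets(dmps, co$m, lab)
  degs <- call_degs(co$counts, lab)
  panels <- distill_panels(degs, co$manifest, sets, co$m, co$counts, lab)

  truth_broad <- co$truth$genes$gene_id[co$truth$genes$panel_flag]
  truth_strict <- co$truth$genes$gene_id[co$truth$genes$strict_panel_flag]
  pr_b <- set_pr(panels$broad$gene, truth_broad)
  expect_gte(pr_b$recall, 0.9)
  expect_gte(pr_b$precision, 0.9)
  expect_setequal(intersect(panels$strict$gene, truth_strict),
                  truth_strict)

  # structural conservation
  expect_true(all(panels$strict$gene %in% panels$broad$gene))
  expect_true(all(panels$broad$gene %in% degs$gene_id[degs$is_deg]))
  qc <- quadrant_counts(panels$records)
  expect_equal(qc$negative + qc$positive, qc$significant)
  expect_equal(sum(qc$by_quadrant$n), qc$significant)
  # strongly negative coupling puts planted pairs in the negative quadrants
  expect_gt(qc$negative, qc$positive)
})

test_that("a down-regulated gene with a single Set1 TRR probe enters the strict panel", {
  m <- matrix(c(-2, -1, -1.5, 1, 2, 1.5), 1,
              dimnames = list("cg1", sprintf("S%02d", 1:6)))
  labels <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  manifest <- tibble::tibble(probe_id = "cg1", chrom = "chr1", pos = 1,
                             gene = "MEOX1like", subregion = "TSS200",
                             cgi_relation = "Island")
  sets <- tibble::tibble(probe_id = "cg1", set = "Set1")
  degs <- tibble::tibble(gene_id = "MEOX1like", is_deg = TRUE,
                         direction = "down")
  # expression tracks methylation downward in B; constant housekeeping
  # genes anchor the size factors at 1
  counts <- rbind(
    MEOX1like = as.integer(round(2^(8 - 1.5 * m[1, ]))),
    matrix(c(100L, 200L, 400L), 3, 6, byrow = FALSE,
           dimnames = list(paste0("hk", 1:3), NULL)))
  colnames(counts) <- colnames(m)
  panels <- distill_panels(degs, manifest, sets, m, counts, labels)
  expect_equal(panels$strict$gene, "MEOX1like")
  expect_equal(panels$strict$direction, "down")
  expect_equal(panels$strict$sets, "Set1")
})

test_that("empty DEG input yields empty panels with a warning", {
  co <- simulate_cohort(tiny_config(n_probes = 100, n_genes = 30,
                                    seed = 34))
  lab <- truth_labels(co)
  degs <- call_degs(co$counts, lab)
  degs$is_deg <- FALSE
  expect_warning(
    panels <- distill_panels(degs, co$manifest,
                             tibble::tibble(probe_id = character(0),
                                            set = character(0)),
                             co$m, co$counts, lab),
    "empty")
  expect_equal(nrow(panels$broad), 0)
  expect_equal(quadrant_counts(panels$records)$significant, 0)
})

test_that("re-clustering on the strict panel reproduces the reference clusters", {
  co <- simulate_cohort(tiny_config(seed = 35))
  lab <- truth_labels(co)
  reference <- assign_two_clusters(co$m)
  dmps <- call_dmps(co$m, lab)
  sets <- extract_methyl_sets(dmps, co$m, lab)
  degs <- call_degs(co$counts, lab)
  panels <- distill_panels(degs, co$manifest, sets, co$m, co$counts, lab)
  rc <- panel_reclustering(panels$strict, co$m, co$counts, reference)
  expect_true(rc$methylation$exact_match)
  expect_true(rc$expression$exact_match)
  expect_equal(rc$methylation$ari, 1)
  expect_equal(rc$expression$ari, 1)
  expect_error(panel_reclustering(panels$strict[0, ], co$m, co$counts,
                                  reference), "empty")
})
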