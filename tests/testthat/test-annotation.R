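mini_methyl <- function(a_values, b_values, probe = "cg1") {
  n_a <- length(a_values); n_b <- length(b_values)
  m <- matrix(c(a_values, b_values), 1,
              dimnames = list(probe, sprintf("S%02d", seq_len(n_a + n_b))))
  labels <- setNames(rep(c("A", "B"), c(n_a, n_b)), colnames(m))
  list(m = m, labels = labels)
}

dmp_row <- function(probe = "cg1") {
  tibble::tibble(probe_id = probe, u = 0, p_raw = 0.001, p_adj = 0.01,
                 median_m_a = -1, median_m_b = 1,
                 status_a = "hypomethylated",
                 status_b = "hypermethylated", is_dmp = TRUE)
}

test_that("Methyl-Set criteria use strict all-sample inequalities", {
  fx <- mini_methyl(c(-1, -2, -0.1), c(0.5, 2))
  sets <- extract_methyl_sets(dmp_row(), fx$m, fx$labels)
  expect_equal(sets$set, "Set1")

  # one positive A value disqualifies
  fx2 <- mini_methyl(c(-1, 0.1), c(1, 2))
  expect_equal(nrow(extract_methyl_sets(dmp_row(), fx2$m, fx2$labels)), 0)

  # a value of exactly zero disqualifies
  fx3 <- mini_methyl(c(-1, 0), c(1, 2))
  expect_equal(nrow(extract_methyl_sets(dmp_row(), fx3$m, fx3$labels)), 0)

  # mirrored pattern lands in Set2
  fx4 <- mini_methyl(c(2, 1), c(-0.5, -2, -1))
  expect_equal(extract_methyl_sets(dmp_row(), fx4$m, fx4$labels)$set,
               "Set2")
})

test_that("set sizes on the fixture equal the noise-verified planted flags", {
  co <- simulate_cohort(tiny_config(seed = 23))
  lab <- truth_labels(co)
  dmps <- call_dmps(co$m, lab)
  sets <- extract_methyl_sets(dmps, co$m, lab)
  truth1 <- co$truth$probes$probe_id[co$truth$probes$set1_flag]
  truth2 <- co$truth$probes$probe_id[co$truth$probes$set2_flag]
  expect_setequal(sets$probe_id[sets$set == "Set1"], truth1)
  expect_setequal(sets$probe_id[sets$set == "Set2"], truth2)
  expect_false(any(duplicated(sets$probe_id)))  # Set1 and Set2 disjoint
  expect_lte(nrow(sets), sum(dmps$is_dmp))
  # invariant to sample order
  sets_perm <- extract_methyl_sets(dmps, co$m[, sample(ncol(co$m))], lab)
  expect_setequal(sets_perm$probe_id, sets$probe_id)
})

test_that("DMP categorization counts per probe (CGI) and per pair (subregion)", {
  manifest <- tibble::tibble(
    probe_id = c("cg1", "cg1", "cg2"),
    chrom = "chr1", pos = 1:3,
    gene = c("GX", "GY", "GZ"),
    subregion = c("5'UTR", "Body", "TSS200"),
    cgi_relation = c("OpenSea", "OpenSea", "OpenSea"))
  dmps <- dplyr::bind_rows(dmp_row("cg1"), dmp_row("cg2"))
  cats <- categorize_dmps(dmps, manifest)
  expect_equal(cats$cgi$category, "OpenSea")
  expect_equal(cats$cgi$n, 2L)        # cg1 counted once despite 2 genes
  expect_equal(cats$cgi$frac, 1)
  expect_equal(sum(cats$subregion$n), 3L)  # one per (probe, gene) pair
  expect_equal(sum(cats$subregion$frac), 1)
  # unannotated probes fall into an intergenic bucket
  dmps3 <- dplyr::bind_rows(dmps, dmp_row("cg9"))
  cats3 <- categorize_dmps(dmps3, manifest)
  expect_true("intergenic" %in% cats3$cgi$category)
})

test_that("TRR restriction keeps only regulatory-region pairs", {
  manifest <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg2", "cg3"),
    chrom = "chr1", pos = 1:4,
    gene = c("GA", "GX", "GY", "GB"),
    subregion = c("Body", "5'UTR", "Body", "TSS1500"),
    cgi_relation = "Island")
  trr <- trr_probes(c("cg1", "cg2", "cg3"), manifest)
  expect_equal(nrow(trr), 2)  # cg1 Body-only excluded; cg2 kept for GX only
  expect_setequal(trr$gene, c("GX", "GB"))
  summ <- attr(trr, "summary")
  expect_equal(sum(summ$frac), 1)
})

test_that("gene TRR median aggregates per sample", {
  m <- matrix(c(1, 5, 3, 7), 2, 2,
              dimnames = list(c("cg1", "cg2"), c("S1", "S2")))
  manifest <- tibble::tibble(
    probe_id = c("cg1", "cg2"), chrom = "chr1", pos = 1:2, gene = "GX",
    subregion = c("TSS200", "5'UTR"), cgi_relation = "Island")
  med <- gene_trr_median_m(m, manifest, "GX")  # per-sample median of 1,5 and 3,7
  expect_equal(med, c(S1 = 3, S2 = 5))
  # single probe: identity
  med1 <- gene_trr_median_m(m, manifest, "GX", probes = "cg1")
  expect_equal(med1, c(S1 = 1, S2 = 3))
  expect_error(gene_trr_median_m(m, manifest, "GZ"), "GZ")
})

test_that("whole-TRR consistency requires every probe to share the pattern", {
  m <- matrix(c(2, 1, 2, -1, -2, -1,      # cg1: Set2 pattern
                0.5, 1, 2, 0.7, 1, 0.4),  # cg2: same sign both clusters
              2, 6, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), sprintf("S%02d", 1:6)))
  labels <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  man1 <- tibble::tibble(probe_id = "cg1", chrom = "chr1", pos = 1,
                         gene = "GX", subregion = "TSS200",
                         cgi_relation = "Island")
  flag1 <- whole_trr_consistent("GX", m, labels, man1)
  expect_true(as.logical(flag1))
  expect_equal(attr(flag1, "pattern"), "Set2")

  man2 <- dplyr::bind_rows(man1,
                           tibble::tibble(probe_id = "cg2", chrom = "chr1",
                                          pos = 2, gene = "GX",
                                          subregion = "5'UTR",
                                          cgi_relation = "Island"))
  expect_false(as.logical(whole_trr_consistent("GX", m, labels, man2)))
  # the TRR-median alternative can still pass when the median keeps the sign
  expect_true(as.logical(whole_trr_consistent("GX", m, labels, man2,
                                              rule = "median")))
})

test_that("planted strict genes are exactly the whole-TRR-consistent panel genes", {
  co <- simulate_cohort(tiny_config(seed = 24))
  lab <- truth_labels(co)
  genes <- co$truth$genes
  flags <- vapply(genes$gene_id[genes$panel_flag], function(g) {
    as.logical(whole_trr_consistent(g, co$m, lab, co$manifest))
  }, logical(1))
  expect_setequal(names(flags)[flags],
                  genes$gene_id[genes$strict_panel_flag])
})
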