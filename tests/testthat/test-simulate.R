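test_that("identical configs give bit-identical cohorts", {
  a <- simulate_cohort(tiny_config(seed = 9))
  b <- simulate_cohort(tiny_config(seed = 9))
  expect_identical(a$m, b$m)
  expect_identical(a$counts, b$counts)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$samples, b$samples)
  c <- simulate_cohort(tiny_config(seed = 10))
  expect_false(identical(a$m, c$m))
})

test_that("manifest uses closed vocabularies, covers all genes and partitions probes", {
  cfg <- tiny_config(n_probes = 400, n_genes = 80)
  man <- generate_manifest(cfg)
  expect_true(all(man$subregion %in%
                    c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                      "ExonBnd", "3'UTR")))
  expect_true(all(man$cgi_relation %in%
                    c("Island", "Shore-N", "Shore-S", "Shelf-N", "Shelf-S",
                      "OpenSea")))
  expect_gte(dplyr::n_distinct(man$gene), 80)
  # CGI relation is a probe-level partition: one relation per probe,
  # categories sum to n_probes
  per_probe <- dplyr::distinct(man, probe_id, cgi_relation)
  expect_equal(nrow(per_probe), 400)
  expect_equal(sum(table(per_probe$cgi_relation)), 400)
  expect_error(generate_manifest(tiny_config(n_probes = 10, n_genes = 50)),
               "n_genes")
})

test_that("multi-gene probe count reproduces under the same seed", {
  cfg <- tiny_config(n_probes = 1000, n_genes = 100, frac_multi_gene = 0.1,
                     seed = 5)
  m1 <- generate_manifest(cfg)
  m2 <- generate_manifest(cfg)
  multi1 <- sum(table(m1$probe_id) > 1)
  expect_identical(multi1, sum(table(m2$probe_id) > 1))
  expect_gt(multi1, 0)
})

test_that("planted panel genes carry at least two TRR probes", {
  co <- simulate_cohort(tiny_config(seed = 3))
  trr_sub <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  panel_genes <- co$truth$genes$gene_id[co$truth$genes$panel_flag]
  expect_gt(length(panel_genes), 0)
  n_trr <- co$manifest |>
    dplyr::filter(gene %in% panel_genes, subregion %in% trr_sub) |>
    dplyr::count(gene)
  expect_setequal(n_trr$gene, panel_genes)
  expect_true(all(n_trr$n >= 2))
})

test_that("noiseless Set probes sit strictly on opposite sides of zero", {
  cfg <- tiny_config(m_noise_sd = 0, seed = 2)
  man <- generate_manifest(cfg)
  sim <- simulate_methylation(cfg, man)
  in_a <- sim$samples$cluster_truth == "A"
  s1 <- sim$probes$probe_id[sim$probes$set1_flag]
  expect_gt(length(s1), 0)
  expect_true(all(sim$m[s1, in_a] < 0))
  expect_true(all(sim$m[s1, !in_a] > 0))
  s2 <- sim$probes$probe_id[sim$probes$set2_flag]
  expect_true(all(sim$m[s2, in_a] > 0))
  expect_true(all(sim$m[s2, !in_a] < 0))
  expect_false(any(sim$probes$set1_flag & sim$probes$set2_flag))
})

test_that("sign flags are verified on realized noisy values", {
  for (s in c(1, 7, 19)) {
    cfg <- tiny_config(m_noise_sd = 1.5, seed = s)
    man <- generate_manifest(cfg)
    sim <- simulate_methylation(cfg, man)
    in_a <- sim$samples$cluster_truth == "A"
    s1 <- sim$probes$probe_id[sim$probes$set1_flag]
    if (length(s1) > 0) {
      expect_true(all(apply(sim$m[s1, in_a, drop = FALSE], 1, max) < 0))
      expect_true(all(apply(sim$m[s1, !in_a, drop = FALSE], 1, min) > 0))
    }
  }
})

test_that("planted DMPs have the configured between-cluster mean gap", {
  cfg <- tiny_config(m_noise_sd = 0, delta_m = 4, seed = 8)
  man <- generate_manifest(cfg)
  sim <- simulate_methylation(cfg, man)
  in_a <- sim$samples$cluster_truth == "A"
  gap <- abs(rowMeans(sim$m[, !in_a]) - rowMeans(sim$m[, in_a]))
  expect_true(all(gap[sim$probes$dmp_flag] >= 4 - 1e-12))
  expect_true(all(gap[!sim$probes$dmp_flag] < 1e-12))
})

test_that("zero-dispersion counts are Poisson-like (variance ~ mean)", {
  cfg <- tiny_config(n_probes = 300, n_genes = 300, nb_dispersion = 0,
                     frac_deg = 0, frac_dmp = 0, seed = 6)
  co <- simulate_cohort(cfg)
  norm <- sweep(co$counts, 2, co$truth$size_factors, `/`)
  m <- rowMeans(norm)
  v <- apply(norm, 1, var)
  ratio <- mean(v / m)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("expression coupling makes panel genes anticorrelate with TRR methylation", {
  co <- simulate_cohort(tiny_config(seed = 4))
  expr <- sweep(co$counts, 2, co$truth$size_factors, `/`)
  panel <- co$truth$genes$gene_id[co$truth$genes$panel_flag]
  rs <- vapply(panel, function(g) {
    med <- gene_trr_median_m(co$m, co$manifest, g)
    cor(med, expr[g, ])
  }, numeric(1))
  expect_true(all(rs < -0.7))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_dmp = 1.2), "fraction")
  expect_error(sim_config(n_samples_a = 1, n_samples_b = 1), "4 samples")
  expect_error(sim_config(log2fc_planted = -1), "log2fc")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(sim_config(median_pfs_b = 0), "positive")
  expect_error(sim_config(frac_set1 = 0.7, frac_set2 = 0.7), "exceed 1")
  cfg0 <- tiny_config()
  cfg0$delta_m <- -1
  expect_error(simulate_methylation(cfg0, generate_manifest(tiny_config())),
               "delta_m")
})

test_that("fixtures round-trip losslessly and are checksum-stable", {
  co <- simulate_cohort(tiny_config(n_probes = 120, n_genes = 40, seed = 13))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(co, d1)
  write_fixture(simulate_cohort(tiny_config(n_probes = 120, n_genes = 40,
                                            seed = 13)), d2)
  back <- read_cohort(d1)
  expect_equal(back$m, co$m)
  expect_identical(back$counts, co$counts)
  expect_equal(as.data.frame(back$manifest), as.data.frame(co$manifest))
  for (f in basename(p1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(write_fixture(structure(list(m = NULL), class = "methx_cohort"),
                             d1), "incomplete")
})
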