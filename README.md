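# methxpanel

Integrative methylome–transcriptome clustering and prognostic gene-panel
distillation for small tumor cohorts.

## The problem

Adamantinomatous craniopharyngioma (ACP) and similar rare tumors are
profiled in cohorts of only a dozen or so patients, typically with an
Illumina EPIC methylation array (M-values, `M = log2(methylated /
unmethylated)`) and bulk RNA-seq counts per gene. The analytical question
is whether the cohort splits into molecular subgroups that (a) appear
independently in both omics layers, (b) can be traced to promoter
methylation driving expression, and (c) differ in outcome — and, if so,
whether the evidence can be distilled into a small gene panel that
re-identifies the subgroups on its own.

`methxpanel` implements that whole chain as composable, tested R
functions:

1. **Probe QC** — drop probes with detection *P* > 0.01 in any sample, on
   sex chromosomes, overlapping SNPs, or cross-reactive.
2. **Two-cluster discovery** — classical (Torgerson) MDS on Euclidean
   distances and PCA, followed by a deterministic Ward (`ward.D2`) cut at
   k = 2 on the top-2 coordinates, run independently on M-values and on
   variance-stabilized counts `log2(count / size_factor + 1)`; concordance
   between the layers is scored by adjusted Rand index.
3. **Differential methylation** — per-probe exact Mann–Whitney U between
   clusters, Benjamini–Hochberg adjustment, DMPs at `P_adj ≤ 0.05`;
   per-cluster hypo/hyper status from the sign of the cluster median
   M-value; CGI-context and gene sub-region composition with chi-square
   association tests.
4. **Methyl-Sets** — sign-consistent DMPs: Set1 has every cluster-A
   M-value `< 0 <` every cluster-B value; Set2 is the mirror image.
5. **Differential expression** — a self-contained negative-binomial Wald
   test (median-of-ratios size factors, method-of-moments dispersions
   shrunk 50 % toward a monotone dispersion–mean trend), DEGs at
   `P_adj ≤ 0.01` and `|log2FC| ≥ 2`.
6. **Integration** — two Pearson-correlation cascades over all samples
   with the rule `|r| ≥ 0.7` and `P_adj ≤ 0.05`: Approach I starts from
   the Methyl-Sets, Approach II from the DEGs. Approach II distills a
   **broad** panel (DEGs with a significantly correlated sign-consistent
   TRR probe — TRR = TSS1500/TSS200/5'UTR/1stExon) and a **strict** panel
   (broad genes whose *entire* TRR is sign-consistent), then re-clusters
   the cohort on each panel to validate it.
7. **Survival** — Kaplan–Meier progression-free survival per cluster and
   the log-rank test; tumor volume as `width × height × length × 0.5`.

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates the
study design — two latent clusters of 9 and 6 samples, planted DMPs with
sign-consistent subsets, NB counts with planted DEGs, panel genes whose
expression is negatively coupled to their TRR methylation, and
exponential PFS with cluster-specific medians — with a full ground-truth
table, so every stage is testable without any data download.

## Worked example

```r
library(methxpanel)

cohort <- simulate_cohort(sim_config(seed = 7))
cohort
#> <methx_cohort>
#>   2000 probes x 15 samples (M-values); 600 genes (counts)
#>   planted: 200 DMPs (20 Set1, 60 Set2), 60 DEGs, 40 panel genes (10 strict)

report <- run_pipeline(cohort)
report
#> <methx_report>
#>   clusters: 9 (A) + 6 (B); concordance ARI 1.000, exact match TRUE
#>   DMPs: 209 (Set1 20, Set2 60); DEGs: 60 (48 up, 12 down)
#>   pairs: 145 tested, 81 significant (80 negative); panels: broad 40, strict 10
#>   PFS medians: 59.14 vs 75.17 months; log-rank p = 0.913
```

Reading the output: the methylation- and expression-based clusterings put
exactly the same 9 + 6 samples together (`ARI 1.000, exact match TRUE`).
The DMP caller finds 209 probes (200 planted plus BH-level noise), and
the sign-consistent Set1/Set2 and both panels are recovered exactly
(planted: 40 broad, 10 strict). Of the 81 significant probe–DEG pairs,
80 correlate in the negative direction expected for promoter methylation
(hypomethylated/up-regulated or hypermethylated/down-regulated in cluster
B). At n = 15 with 20 % censoring, the Kaplan–Meier medians are noisy and
the log-rank comparison is far from significant — small-cohort survival
comparisons are reported, not oversold.

Per-stage results live under `report$stages` (tibbles throughout), and
`glance(report)` / `tidy(report)` give the scalar summary. Plot helpers:
`autoplot()` on embeddings and KM curves, `plot_volcano()`,
`plot_quadrants()`.

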