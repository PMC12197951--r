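---
title: "Methods: integrative methylome–transcriptome clustering and panel distillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylome–transcriptome clustering and panel distillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methxpanel)
```

# Scope and model

`methxpanel` analyses a small tumor cohort profiled on two omics layers:
an EPIC-array methylation matrix of M-values (probes × samples, where
`M = log2(methylated/unmethylated)`, so `M = 0` corresponds to 50 %
methylation) and an RNA-seq count matrix (genes × samples). The pipeline
asks three questions in sequence: do the samples split into two
molecular clusters that agree across both layers; which probes and genes
differ between the clusters and how are they coupled; and can the
coupling evidence be distilled into a compact gene panel that recovers
the clusters on its own and stratifies progression-free survival (PFS).

The package deliberately starts *downstream* of raw data processing: it
consumes M-values, detection P-values and gene counts, not IDATs or
FASTQs. Quantile normalization, alignment and counting belong to
upstream tools.

# Stages, assumptions, and parameters

## Probe filtering

Probes are removed when they fail detection (`P > 0.01`) in **any**
sample, sit on a sex chromosome (`chrX/X/chrY/Y` manifest spellings all
recognised), overlap a SNP, or are listed as cross-reactive. Each probe
is counted once, under the first rule that removes it, so the report's
removals plus retentions always equal the input. The any-sample
detection rule is the conservative common practice; a
fraction-of-samples rule would retain more probes and is worth a
sensitivity analysis when detection failures are clustered by sample.

## Two-cluster discovery

Both layers are embedded with classical (Torgerson) multidimensional
scaling on Euclidean distances — `B = -1/2 J D^2 J`, top eigenpairs,
coordinates scaled by the square root of the eigenvalues — and,
equivalently for Euclidean inputs, PCA. For expression, the clustering
input is the shifted log of size-factor-normalized counts,
`log2(count/sf + 1)`. This transform is deterministic and
dependency-free; it is *not* the fitted dispersion-trend VST of
reference DE tools, a deliberate simplification confined to the
clustering input, where only relative distances matter.

Cluster membership itself is not read off a plot: a Ward (`ward.D2`)
agglomerative tree over the top-2 embedding coordinates is cut at two
groups. This is deterministic, seed-free, and standard for compact
clusters. The larger cluster is labelled A (ties broken toward the
cluster holding the lexicographically smallest sample id). Confidence is
reported as the mean silhouette width computed in the **full feature
space** (not the flattering 2-D view); values below 0.25 are flagged
low-confidence. Clustering on all features instead of the 2-D
coordinates is available via `full_matrix = TRUE`.

## Differential methylation

Each probe's M-values are compared between clusters with the
Mann–Whitney U test — exact enumeration p-values whenever
`n_A + n_B <= 20` with no ties (always the case for continuous M-values
at cohort scale), the tie- and continuity-corrected normal approximation
otherwise — followed by Benjamini–Hochberg adjustment across all tested
probes. DMPs are `P_adj <= 0.05`. Per-cluster status is the sign of the
cluster median M-value; a median of exactly 0 counts as hypermethylated
(a documented tie rule that cannot affect the strict-inequality
Methyl-Sets). The rank test is applied per probe to the two clusters'
sample values; a test "on medians" alone is not a defined procedure, so
the medians are reported as summaries, not tested.

## Methyl-Sets

Set1 collects DMPs whose M-values satisfy `max_A(M) < 0 < min_B(M)`
over **every** sample; Set2 is the mirror image. The inequalities are
strict and evaluated on raw per-sample values, so a single sample at
exactly 0 disqualifies a probe. These are the probes whose methylation
*state* (not just level) flips between clusters; everything else —
typically the large majority of DMPs — shares its state across clusters.

## Differential expression

The NB Wald test is intentionally self-contained and deterministic:

* size factors by median-of-ratios (genes with any zero excluded from
  the reference);
* per-cluster normalized means with a 0.5 pseudo-count;
  `log2FC = log2(mean_B/mean_A)`;
* per-gene dispersion `alpha` by method-of-moments from the pooled
  within-cluster variance, floored at `1e-8`, then shrunk 50 % toward a
  nonincreasing isotonic dispersion–mean trend;
* Wald statistic `log2FC / SE` with the delta-method standard error
  `Var(log q) = q·mean(1/sf)/(n·q^2) + alpha/n` per cluster, two-sided
  normal p, BH adjustment;
* DEGs at `P_adj <= 0.01` **and** `|log2FC| >= 2`.

Compared to reference NB implementations this omits Cook's outlier
filtering, independent filtering, and likelihood-based dispersion
estimation. On simulated cohorts the fold-change estimates track DESeq2
closely (checked in the test suite), but on real data counts near the
significance boundary can differ; the fold-change floor of 2 makes the
call robust to most of that. Genes with zero counts everywhere are
excluded from testing and reported as such.

## Correlation integration and the panels

All correlations are Pearson, computed across the **pooled** sample set
(both clusters; at the design scale of 15 samples a within-cluster
correlation would be meaningless), with `p` from the t transform on
`n - 2` df, and significance defined as `|r| >= 0.7` and
`P_adj <= 0.05`.

*Approach I* (methylation-driven) takes the Methyl-Set probes' TRR
(probe, gene) pairs — TRR meaning TSS1500, TSS200, 5'UTR or first exon —
and splits the genes into the DEG overlap, labelling each gene `typical`
when the direction matches the canonical promoter logic in cluster B
(hypomethylated→up, hypermethylated→down) and `atypical` otherwise, and
a non-DEG remainder for which per-probe and TRR-median correlations are
reported.

*Approach II* (expression-driven) correlates every (TRR probe, DEG)
pair, with **one BH family across all stage-1 pairs** (restricting to
Methyl-Set pairs afterwards can then never increase an adjusted p), and
labels each pair's quadrant — Hypo/Hyper × Up/Down with cluster B as the
reference. The **broad** panel is the DEGs with at least one significant
Methyl-Set pair; the **strict** panel keeps broad genes whose *every*
TRR probe individually shows the same Set pattern. The probe-wise
reading of "whole-TRR consistency" is the strict one; a TRR-median-sign
alternative is available (`rule = "median"`). Stage 1 uses TRR probes
only by default; `all_subregions = TRUE` widens it.

Panel validity is then tested structurally: the clustering is re-run on
the panel's probes (M-values) and genes (VST expression) alone, and
compared to the reference clustering by adjusted Rand index and an
exact-match flag.

## Survival

Kaplan–Meier product-limit curves per cluster with the convention that
at tied times events precede censorings. The median is the first time
the curve reaches 0.5 — reported as `NA`, not infinity, when never
reached, which at cluster sizes of 6–9 is common and worth stating
plainly. Groups are compared with the standard log-rank chi-square on
1 df. Tumor volume is `width × height × length × 0.5` cm³. All PFS
inputs are treated as months.

# The synthetic cohort generator

`sim_config()` defines the study conditions; `simulate_cohort()` draws
them. Defaults emulate the designed cohort: clusters of 9 + 6 samples;
10 % of probes planted as DMPs with a between-cluster M gap of
`delta_m = 4` and Gaussian noise `sd = 0.5`; 10 % of those DMPs made
Set1-sign-consistent and 30 % Set2 (placed at `±delta_m/2` around zero);
10 % of genes planted as DEGs at `|log2FC| = 3` (80 % up in cluster B)
on NB counts with dispersion 0.1 and lognormal size factors; panel genes
coupled to their realized TRR median M-value with slope
`coupling_strength = -1` (induced `|log2FC| ≈ 4`); exponential PFS with
medians 140.1 and 25.1 months and 20 % censoring independent of cluster.
One global seed drives a named sub-stream per component, so each
component is reproducible on its own and identical configs give
bit-identical cohorts. Where the design gives no quantitative guidance
(noise sd, dispersion, coupling slope), the defaults were chosen once
for realistic effect-to-noise ratios at array/RNA-seq scale and are not
tuned thereafter.

Three generator choices are deliberate and worth knowing:

* M-values are simulated directly on the M scale with Gaussian noise —
  the pipeline consumes M-values and the Set criteria are sign rules on
  M, so a beta-scale detour would add nothing.
* Sign-consistency flags are assigned only after verifying the
  *realized* noisy values, so the truth table is exact and set
  extraction can be tested with equality, not tolerance.
* Planted panel genes' TRR probes are exactly their dedicated
  sign-consistent probes; sign-consistent probes not attached to a panel
  gene are annotated outside the TRR, and the non-strict fraction of
  panel genes receives one extra non-differential TRR probe that breaks
  whole-TRR consistency. This makes the planted broad/strict panel truth
  exact, so recall and precision are measurable rather than fuzzy.

What the generator does **not** emulate: batch effects, cell-type
composition, beta-value heteroscedasticity, probe-probe spatial
correlation, expression covariance beyond the planted coupling, and
non-exponential hazards. Passing tests therefore demonstrate that the
pipeline's logic is correct and calibrated under its stated model — not
that real cohorts will show effects this clean.

# Numerical choices and degenerate inputs

* Exact-0 M-values: disqualify a probe from the Methyl-Sets; a cluster
  median of 0 counts as hypermethylated.
* `|r| = 1` returns `p = 0`; zero-variance vectors are an error, not an
  `NA`.
* MDS truncates negative eigenvalues to zero with a warning;
  rank-deficient requests are padded/reduced with a warning; PCA of a
  constant matrix returns all-zero scores with a warning.
* Chi-square tests refuse zero expected counts and advise merging
  categories; no continuity correction (matching the large-table use).
* All-zero genes are excluded from DE testing; the all-zero-in-every-
  sample case is reported with `tested = FALSE`.
* Size factors are defined up to a common scale; comparisons are made at
  geometric mean 1.
* Pipeline reports are pure functions of (input, thresholds): rerunning
  with the same cohort and seed reproduces byte-identical JSON.

# Test and verification scale

The suite verifies the statistics against independent oracles (full
enumeration for the exact Mann–Whitney, hand step-up for BH, the direct
chi-square and Pearson formulas, classical-scaling equivalence of MDS
and PCA, closed-form exponential medians for KM) and the pipeline
against the generator's ground truth. Problem sizes were chosen as the
smallest that make the statistical assertions sharp: null calibration
uses 10,000 probes × 2,000 genes in one cohort; parameter recovery runs
the full pipeline across 10 seeds at 2,000 probes × 600 genes; survival
oracles use 5,000 samples per cluster. The low-power behaviour of the
log-rank test at 9-vs-6 with 20 % censoring is itself verified by
simulation: with cluster PFS medians of 140.1 vs 25.1 months the test
rejects in roughly three quarters of replicates, so a non-significant
log-rank at this design size is entirely plausible even under a real
effect.

# Known limitations

* The NB Wald stage is a documented simplification; accession-scale DEG
  counts from reference implementations will differ at the margins.
* The BH family for Approach II stage 1 is the full pair set; per-gene
  families are a defensible alternative (flag available) and change the
  panel at the boundary.
* Whether stage-1 pairs should include non-TRR probes of DEGs is
  ambiguous in common practice; the default is TRR-only with an
  `all_subregions` escape hatch.
* Two-group discovery is fixed at k = 2 by design; the package does not
  attempt model selection over k, consensus clustering, or non-linear
  embeddings.
* Survival comparisons at n = 15 have limited power and wide median
  uncertainty; the package reports undefined medians as `NA` rather
  than extrapolating.
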