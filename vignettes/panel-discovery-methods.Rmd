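---
title: "Methods: multi-omics biomarker panel discovery with stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics biomarker panel discovery with stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelomics)
```

# Scope and model

`panelomics` discovers small diagnostic biomarker panels from matched
case-control cohorts measured on three fecal omics layers — 16S taxon
counts, protein spectral counts and amino-acid concentrations — and
characterizes their performance honestly. The workflow for one two-group
comparison (say CRC vs control) is:

1. align samples across layers and restrict to the two groups;
2. autoscale each layer (per-feature mean 0, SD 1, `n - 1` denominator)
   and summarize its variation by PCA;
3. run combined LASSO / elastic-net **stability selection** per layer;
4. retain the **first quartile** of ever-selected features;
5. fit and evaluate a logistic **panel model** per layer and, after
   pooling the per-layer selections, a second-stage cross-omics panel;
6. compare against a hemoglobin-subunit **reference panel** (the stand-in
   for fecal immunochemical testing);
7. integrate the selected features into a thresholded **correlation
   network** across layers.

Each stage is exposed as an exported function; `run_comparison()`
orchestrates them under a single seed with stage-indexed substreams.

# Stability selection

For a penalty $\lambda$ and mixing parameter $\alpha$, the penalized
logistic objective (intercept unpenalized, $1/n$ scaling) is

$$
-\tfrac1n \sum_i \left[ y_i \eta_i - \log(1 + e^{\eta_i}) \right]
  + \lambda \left[ \alpha \lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2} \lVert\beta\rVert_2^2 \right],
\qquad \eta_i = \beta_0 + x_i^\top \beta .
$$

LASSO is $\alpha = 1$; the elastic-net arm uses $\alpha = 0.5$ by default
(configurable — the mixing weight is a genuinely open choice and 0.5
splits the difference between sparsity and grouped selection of
correlated features). Fits are computed by coordinate descent (glmnet),
which yields exact zeros where the L1 subgradient condition holds;
$\lambda = 0$ is an ordinary ML logistic fit, and any
$\lambda \ge \lambda_{\max} = \max_j |x_j^\top (y - \bar y)| / (n\alpha)$
returns the null model exactly.

The penalty grid has 50 points, log-spaced from $\lambda_{\max}$ down to
$10^{-3}\lambda_{\max}$. Expressing the grid as *fractions of the
data-derived maximal penalty* makes the tuning range scale-free; a
literal fixed interval such as $[0, 1]$ is not, because $\lambda_{\max}$
moves with the data.

**Penalty tuning.** Each candidate $\lambda$ is scored by mean held-out
AUC over stratified cross-validation folds (10 by default, reduced with a
warning when a class has fewer samples than folds). The chosen penalty is
the *largest* $\lambda$ whose mean AUC is within one standard error of
the best — the usual 1-SE convention. Ties toward the sparser model are
the point: with tiny folds, per-fold AUC is granular and the maximum of
30-50 noisy means is biased upward, so a plain argmax chases fold noise
and returns spuriously dense models on null data. Even with the 1-SE
rule, pure-noise data yield a small nonzero support in a minority of
runs; this is a property of AUC-based tuning at these sample sizes, not
of the implementation, and the frequency aggregation below is what
ultimately separates signal from noise.

**Resampling.** `n_iterations` (default 100) independent stratified
75/25 re-splits are drawn; on each training part both arms are tuned and
fit, and the support (nonzero coefficients) of each arm is recorded. The
default is re-splitting rather than bootstrap resampling (a bootstrap
mode is available via `penalty_config(resample = "bootstrap")`) because
re-splits keep every training point distinct, which the downstream
cross-validation assumes. Per-feature frequencies are accumulated for
each arm; the combined frequency is their sum (equivalently their mean;
a union-based combination is available via `combine = "union"`).

**First-quartile retention.** Among features selected at least once, the
selected set is those whose combined frequency reaches the 75th
percentile of the positive frequencies, boundary ties included, ordered
by frequency then ID so output is deterministic.

One caveat worth stating plainly: on a *fixed* cohort, the noise feature
most correlated with the labels in that cohort is genuinely selected
across many re-splits — resampling a fixed dataset cannot wash out
in-sample correlation. Stability frequencies therefore rank features
*within* a cohort; the permuted-label null (below) is the guard against
over-interpreting them, and the test suite checks that permuting labels
collapses planted-feature frequencies to the noise band.

# Panel evaluation

The selected features are refit as an unpenalized logistic model. Under
(quasi-)separation — common for strong panels in small cohorts — the ML
fit diverges, so the fit falls back to a tiny ridge (1e-6) penalty and is
flagged.

Reported quantities:

* **AUC (test)** — the panel is fit on a stratified 75% split and scored
  on the held-out 25%. This is the headline number.
* **AUC (apparent)** — full-data resubstitution AUC, reported and
  labeled because small-cohort studies often print it; it is optimistic.
* **Bootstrap AUC distribution** — stratified bootstrap resamples,
  refit, scored on the out-of-bag samples (resubstitution per iteration
  is available by flag). Out-of-bag scoring avoids the optimism of
  evaluating on the resample itself.
* **Permuted-label ("random") AUC distribution** — labels are permuted,
  the panel refit on a stratified 75% of the permuted data and scored on
  the held-out 25%. The mean locates chance performance.
* **Sensitivity / specificity** at the threshold maximizing Youden's J
  (ties toward higher specificity); the threshold rule is a design
  choice, as no rule is canonical.

AUC is the Mann-Whitney statistic with half credit for ties. For
single-feature screening (`feature_auc()`) the orientation is normalized
so AUC ≥ 0.5, recording the flip — a marker can be diagnostic in either
direction. Model scores (`compute_auc()`) are *never* flipped: flipping
would fold the permutation null upward around 0.5 and bias its mean to
~0.6 at these test-set sizes, destroying its meaning as a chance
reference.

The reference panel (`reference_panel_auc()`) runs the four hemoglobin
subunit IDs through exactly the same evaluation path. The synthetic
proteome names its four most abundant baseline ranks after these
subunits, so the comparison works out of the box on synthetic data; they
are synthetic stand-ins, not measured hemoglobin.

# Beta-binomial differential test

Spectral counts are overdispersed relative to the binomial, so
per-protein differences in count proportions are tested by a
likelihood-ratio test under a beta-binomial model, parameterized by a
proportion $p$ and the intra-class correlation $\phi \in [0, 1)$
($\phi \to 0$ recovers the binomial). The null fits a common $(p, \phi)$
to both groups; the alternative fits group-specific proportions with a
shared $\phi$; $2\Delta\ell$ is referred to $\chi^2_1$.

Numerics: the $\phi$-profile can be bimodal (a boundary binomial mode
and an interior overdispersed mode), so the profile is scanned on a
30-point log grid before local refinement; golden-section search over
the whole interval can miss the global maximum. At $\phi = 0$ the pooled
empirical proportion is the exact MLE, which makes the binomial-limit
check against a closed-form two-proportion LRT oracle exact. The inner
proportion maximization is a bounded 1-d optimization (there is no
closed-form beta-binomial proportion MLE at fixed $\phi$; the implied
statistic is the honest profile LRT). All-zero input in both groups is
degenerate and returns $p = 1$ with a flag rather than an error.

Known limitation: with 10 samples per group the $\chi^2_1$ reference is
slightly anti-conservative — the true size at $\alpha = 0.05$ is about
0.065 for well-quantified proteins (verified against an independent
implementation of the same statistic), and conservative for very rare
proteins whose counts carry little information. This is the familiar
small-sample behavior of profile LRTs, not an implementation artifact.

Fold change is $(\bar x_A + c) / (\bar x_B + c)$ with pseudocount
$c = 1$ for spectral counts (0 for concentrations) and a two-sided flag
at threshold 2 (ratio ≥ 2 or ≤ 1/2).

# Diversity

Alpha diversity is Shannon entropy in nats; beta diversity is
Bray-Curtis on relative abundances with a PERMANOVA (999 permutations by
default, `(count + 1)/(n_perm + 1)` p-value) via vegan. The metrics are
the field-standard defaults; both are configurable choices rather than
derived requirements.

# Correlation network

Selected features from all layers are pooled on the autoscaled scale
(pooling both comparison groups' samples) and correlated pairwise —
Pearson by default, Spearman and Kendall for cross-method consistency.
Pearson and Spearman p-values use the t-transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$; Kendall's tau-b uses the tie-corrected
normal approximation. Edges are kept when $|r| \ge 0.3$ **and**
$p < 0.05$; the magnitude threshold is inclusive and the significance
threshold strict, fixed so outputs are bit-reproducible at the
boundaries. No multiple-testing correction is applied to edge p-values
by default (a Benjamini-Hochberg flag exists); isolated selected
features remain as nodes so panels stay visible in the network.

# Synthetic cohort generator

The generator emulates the matched study conditions so that every
downstream stage can be tested against ground truth:

* **Cohort**: 12 CRC / 21 adenoma / 20 control (53 samples), covariates
  (age, sex, BMI, smoking) drawn balanced across groups to mimic
  matching; downstream models use features only.
* **Microbiota**: 225 taxa; per-sample depth log-normal with median
  23,041 reads; compositions Dirichlet-multinomial with concentration
  `baseline / overdispersion` (default overdispersion 0.02; 0 is the
  multinomial limit) over a Zipf rank-abundance baseline. Planted
  log-fold effects multiply the baseline *before* renormalization, so
  induced effects are compositional, as real differential abundance is.
* **Proteome**: 521 proteins; per-sample total spectra log-normal with
  median 1,500; per-protein counts beta-binomial given the total
  (intra-class correlation 0.005) over a Zipf baseline with exponent
  0.9 summing to 0.9. These constants were fixed once, analytically, so
  that the expected number of detected (nonzero) proteins per sample is
  ~170, matching the emulated study's median of 169 (range 90-281).
* **Amino acids**: 44 features, log-normal with a spread of baseline
  log-means and log-SD 0.6; a missing-at-random quantification mask with
  detection probabilities ramping 0.98 → 0.20 (sum ≈ 26) reproduces a
  median of ~26 quantified amino acids per sample, recorded as 0
  concentration when unquantified.
* **Latent factors**: a per-sample standard-normal factor perturbs each
  loaded feature on its log analysis scale, replacing the standardized
  column $z$ by $\sqrt{1-w^2}\,z + w f$ with effective loading
  $w = \text{loading} \times \sqrt{\text{factor variance}}$. Any two
  features on the same factor then have expected log-scale correlation
  $w_i w_j$, recorded as truth for network recovery. A feature may load
  on at most one factor, keeping the closed form exact. Zero factor
  variance leaves tables bit-identical.

One root seed drives per-layer RNG substreams, so the cohort is
bit-reproducible and layers can be regenerated independently.

What the generator does *not* emulate: batch effects, longitudinal
sampling, taxon co-occurrence structure beyond the planted factors,
protein-protein abundance correlations, and the heavy zero-inflation
patterns of real 16S data beyond what the Dirichlet-multinomial
produces. Passing tests on synthetic data therefore demonstrate that the
machinery recovers known structure under its own assumptions, not that
it will rank real markers as the original study did.

# Numerical and design choices

* Canonical in-memory orientation is samples-in-rows; TSV files default
  to features-in-rows (QIIME-style) with both orientations supported.
* Normalization is computed on the full comparison dataset before
  splitting, matching the described order of the emulated workflow; this
  leaks means/SDs across the split, so a strict mode (scaler fit on
  training folds) can be added per panel by autoscaling inside the loop
  — the default mirrors fidelity, and the permutation null inherits the
  same treatment so the comparison is fair.
* Missing amino-acid quantifications are encoded as 0 on input; whether
  counts are z-scored directly or after relative-abundance conversion is
  exposed (`microbiota_relative`), defaulting to direct scaling.
* Zero-variance features are dropped with a warning (they carry no
  contrast); degenerate Welch inputs (zero variance both groups, equal
  means) return p = 1.
* The advanced- vs non-advanced-adenoma sub-analysis is the same
  pipeline with different labels plus the sparse-prevalence filter
  (default 0.2) enabled.
* Problem sizes in the test suite: the planted benchmark is 2 groups x
  30 samples, 200 features, 5 planted at standardized effect 1.5 — large
  enough for stable recovery statistics, small enough that the full
  suite runs in minutes. The end-to-end determinism check runs the
  default 53-sample, 790-feature cohort through the complete pipeline
  twice.

# A worked example

```{r example, eval = FALSE}
design <- cohort_design(
  planted = list(planted_signal("proteome", 20, c("CRC", "control"), 2.0),
                 planted_signal("amino_acid", 5, c("CRC", "control"), 1.5)),
  seed = 42)
cohort <- generate_cohort(design)
config <- comparison_config(c("CRC", "control"), seed = 11)
report <- run_comparison(cohort$tables, cohort$meta, config)
print(report)
write_comparison_report(report, "crc_vs_control")
```

The printed report lists per-layer selections, the cross-omics combined
panel with its held-out and apparent AUCs, the permutation-null mean,
the hemoglobin reference AUC, and the network size. All artifacts are
written as TSV/JSON/GraphML; everything except the run log (which
carries wall times) is byte-reproducible under a fixed seed.
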