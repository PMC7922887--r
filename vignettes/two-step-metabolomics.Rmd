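---
title: "Two-step case-control analysis of LC-MS metabolomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step case-control analysis of LC-MS metabolomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabocc)
```

## The problem

Untargeted LC-MS metabolomics compares the small-molecule profiles of two
clinical groups — here the motivating design is a neonatal case-control
study with roughly ten subjects per group and a few thousand RT_mass
features per ionization mode — to find discriminating metabolites and the
pathways they sit in. Such data come with specific nuisances: per-sample
multiplicative dilution (urine especially), features whose response is not
quantitative, missing values, and far more features than samples. The
package implements a complete two-step workflow: a discovery arm on an
untargeted feature table, and a validation arm on a targeted
concentration panel, both built around PLS-DA with stability selection.

`generate_feature_table()` and its companions simulate data with exactly
the statistical structure the pipeline assumes, so every stage is testable
end to end without access to instrument data.

## The intensity model behind the simulator

Log-intensity of feature $j$ in sample $i$ is

$$\log x_{ij} = b_j + \delta_j \, \mathbb{1}[i \in \text{case}] + \log d_i + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with $b_j \sim N(9, 1)$ a feature baseline (about $e^9 \approx 8000$
counts), $\delta_j$ the planted group effect (nonzero only for the
discriminant features, default 2 natural-log units), $d_i$ a per-sample
dilution factor with $\log d_i \sim N(0, 0.3^2)$, and noise
$\sigma = 0.5$ by default. Missing entries are inserted completely at
random (default 5%). Defaults mirror the motivating cohort: 9 cases vs 10
controls, 2394 features in negative mode, pooled-QC samples at nominal
dilutions 1:3, 1:5 and 1:7.

This log-normal multiplicative model is the standard idealization of
LC-MS intensities and makes the assumptions of probabilistic quotient
normalization literally true. Real data deviate in ways the simulator
deliberately does not model: retention-time drift, batch effects,
intensity-dependent missingness, correlated features from adducts and
isotopes, and heavy-tailed noise. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every artifact of real spectra.

A configurable subset of features (planted ones first) receives m/z
values copied from the bundled metabolite table as `[M+H]+` or `[M-H]-`
adduct masses with small ppm jitter (default 2 ppm), so annotation can be
exercised; the remaining m/z are uniform decoys in 50–1200 Da, matching a
typical Q-ToF scanning range.

## Preprocessing

**QC dilution calibration.** Pooled-QC samples injected at known dilution
fractions let us ask, per feature, whether intensity tracks concentration.
`fit_qc_calibration()` regresses QC intensity on the nominal dilution
fraction by ordinary least squares; features with $R^2 < 0.7$ (default),
fewer than three non-missing QC observations, or a non-positive slope are
dropped. `apply_calibration_filter()` optionally divides by the slope
(response-factor correction) so a corrected QC at dilution $d$ has
expectation $d$. Whether the original study corrected intensities or only
filtered features is not determinable from its description; both
behaviors are provided behind the `correct` flag, with correction the
default.

**PQN.** `pqn_normalize()` removes per-sample dilution: the reference is
the feature-wise median over study samples; each sample is divided by the
median of its feature-wise quotients to the reference. The reference
choice (median study profile) is the canonical one. PQN is idempotent and
recovers simulated dilution factors to within a few percent (median
relative error ≈ 3% at $\sigma_{\text{dil}} = 0.3$); note the estimated
factors are identified only up to a common constant, so accuracy is
assessed after rescaling by the median ratio.

**Missingness and scaling.** Features missing in more than half the study
samples are removed; remaining gaps are imputed with half the feature's
minimum observed value, the conventional below-detection-limit stand-in.
Untargeted tables are mean-centered, targeted panels autoscaled (n−1
denominator throughout); zero-variance columns are centered and flagged,
never divided by zero.

## Outlier detection

`detect_outliers()` fits a PCA and tests each sample with Hotelling's
$T^2$ (on the retained score space) and $Q$, the squared reconstruction
residual. The $T^2$ limit at confidence $\gamma$ is
$\frac{A(n-1)(n+1)}{n(n-A)} F_{\gamma}(A, n-A)$; the $Q$ limit uses the
Jackson–Mudholkar approximation from the residual eigenvalues. Defaults:
$\gamma = 0.95$, and the component count is the 80%-variance rule
**capped at 3**. The cap is a deliberate design choice: with $n \ll p$
the 80% rule alone absorbs most of the sample rank into the model,
leaving so few residual eigenvalues that the Jackson–Mudholkar limit
becomes unstable and flags ≥ 1 sample in roughly a quarter of clean
simulated tables; with the cap, clean 19-sample tables show zero flags in
about 97% of simulations, in line with score-plot screening practice.
Outliers are only ever reported, never silently removed.

## Univariate testing

Per feature, a Shapiro–Wilk gate applied to each group separately (the
stricter reading of the gate) routes to the pooled-variance t-test when
both group p-values exceed 0.10, otherwise to the Mann–Whitney test
(exact null when both groups have ≤ 20 observations without ties, normal
approximation with tie and continuity correction otherwise). P-values are
adjusted by Benjamini–Hochberg and features with $q \le \delta$
(default 0.10) are relevant. A Welch flag is available; at cohort scale
the pooled and Welch tests round identically.

## The PLS-DA core

`plsda()` dummy-codes the two classes as a single ±1 column — for two
classes this is equivalent to the two-column coding — autoscales it,
scales the predictors, and extracts latent variables by NIPALS with
deflation (convergence tolerance 1e-10, at most 500 iterations; with a
single response column the inner loop converges in one pass). Class
membership is assigned by two-class LDA with pooled covariance on the
score space; a singular pooled covariance is ridge-regularized with
$\varepsilon = 10^{-8}$ and a warning, and ties break toward the larger
prior, then lexicographically. The fit is verified against an independent
NIPALS implementation to 1e-8 in the test suite.

**Post-transformation.** The fitted score space is rotated by an
orthogonal matrix whose first column is the normalized vector
$T^\top y$: the first rotated score $t_p$ then carries all covariance
with the response and the remaining $t_o$ columns are exactly orthogonal
to it, while fitted values are unchanged (the prediction depends on the
scores only through their span). This gives the familiar
predictive-vs-orthogonal score scatter plot; `plot()` on a fitted model
draws it.

**VIP.** $\mathrm{VIP}_j = \sqrt{p \sum_a s_a (w_{ja}/\|w_a\|)^2 / \sum_a s_a}$
with $s_a$ the response sum of squares explained by component $a$; the
mean of $\mathrm{VIP}^2$ is identically 1, which the tests assert to
1e-10 on every fitted model.

**Model assessment.** The Matthews correlation coefficient summarizes the
2×2 confusion matrix, in fit and under stratified five-fold
cross-validation in which scaling, PLS and LDA are all re-estimated
inside each training fold. Significance comes from permutation of the
class response with full recomputation of the statistic and the add-one
p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$.
The number of latent variables is chosen by maximizing cross-validated
MCC, ties toward the smaller model. Note that with $p \gg n$ the in-fit
MCC is 1 for almost any labelling, so its permutation p-value is
uninformative by construction; the cross-validated MCC is the statistic
that carries evidential weight, and the pipeline reports permutation
p-values for both.

## Stability selection

Relevant features from the multivariate view are those selected
persistently across 500 (default) stratified bootstrap refits, where the
final frequency threshold is the empirical $1-\alpha$ quantile of the
maximum per-feature frequency observed under permutations of the class
response ($\alpha = 0.05$).

The per-subset selection rule required a design decision that the
package's own simulations forced. The textbook rule "VIP ≥ 1" turns out
to carry no information in the $n \ll p$ regime: for any response —
including a permuted one — some feature is the best-aligned with it by
chance and keeps VIP ≥ 1 in essentially every bootstrap subset, so the
maximum null frequency saturates at 1.0 (measured at 30 samples × 500
features for bootstrap counts from 100 to 500) and the calibrated
threshold collapses to 1.0, leaving zero power. The package therefore
calibrates the cutoff within each subset: a feature is selected when its
VIP reaches `max(vip_cutoff, max VIP of one refit of the same subset
with the response permuted)`. Because the permutation is fresh in every
subset, no null feature is persistently favoured; measured null maximum
frequencies drop to 0.08–0.25 while planted features (3 log-unit
effects) retain frequency 1.0. The null rounds use the same bootstrap
count as the observed pass so that observed and null frequencies are
exchangeable; with 20 null rounds the empirical 0.95 quantile is the
19th order statistic, so the realized family-wise level is at most 2/21
rather than exactly 0.05 — a known discreteness of small permutation
nulls.

On simulated data with strong planted effects, the stability-selected
set nests inside the univariate BH-relevant set, mirroring the behaviour
expected when multivariate selection is the stricter filter.

## Annotation and pathway over-representation

`mass_match()` compares an observed m/z against `[M+H]+` / `[M-H]-`
adduct masses (proton mass 1.007276 Da; further adducts can be supplied)
of the bundled metabolite table within a ppm tolerance (default 10 ppm,
appropriate for a Q-ToF), ranking hits by absolute ppm error. The bundled
table is a miniature curated database — the urine and plasma panel
metabolites plus canonical glutathione-pathway members, 82 entries with
monoisotopic masses computed from molecular formulas and simplified
KEGG-style pathway sets (17 pathways). Annotation confidence levels are
recorded metadata, not inferred: identification confidence requires
MS/MS evidence that mass matching cannot supply.

`run_ora()` tests each pathway by the exact hypergeometric upper tail
$P(X \ge k)$ with the bundled database as the default universe, adjusts
by Benjamini–Hochberg across pathways, and flags pathways at
$q \le \delta$ (0.15 untargeted, 0.10 targeted). The reported "impact"
is the hit fraction $k/K$ — an explicitly declared simple stand-in for
topology-based impact measures, which are out of scope. Both raw p and q
are kept in the result so either can be plotted against impact.

## The two pipeline arms

`run_untargeted()` chains calibration (when QC rows are present), PQN,
missingness filtering and imputation, log transform, outlier reporting,
univariate testing ($\delta = 0.10$), component selection by
cross-validated MCC, permutation p-values, stability selection, the
set-union merge of the univariate and multivariate relevant sets (with a
provenance column recording which arm contributed each feature),
annotation, and ORA ($\delta = 0.15$). `run_targeted()` does the same on
a named concentration panel with autoscaling, no annotation (identities
are known), and ORA at $\delta = 0.10$. Both are deterministic given the
seed in `pipeline_config()`; the log-intensity analysis scale is the
natural choice under the multiplicative model and is the default.

## Numerical and design choices, in brief

- Standard deviations use the n−1 denominator everywhere.
- NIPALS: tolerance 1e-10, max 500 iterations; rank exhaustion raises an
  error rather than returning degenerate components.
- PCA sign convention: the largest-magnitude loading entry of each
  component is positive, making fits reproducible across BLAS libraries.
- The Fisher two-sided p sums all tables (fixed margins) whose
  hypergeometric probability is at most that of the observed table, with
  a 1e-7 relative tolerance on the comparison — the convention of
  standard statistical software, verified in the tests against exact
  rational enumeration for every 2×2 table with $N \le 40$.
- Quantiles of permutation nulls use the inverse-ECDF definition
  (`type = 1`), never interpolation.
- Simulation-based tests in the suite run at reduced sizes chosen to keep
  the full suite near ten minutes on one core (e.g. 50 stability
  simulations at 100 bootstrap subsets, 200 permutation-calibration
  replicates at 99 permutations); these sizes are the package's own
  testing choices and are documented in the tests themselves.

## Known limitations

- The annotation stage matches accurate mass only; isomers are
  indistinguishable and the miniature database cannot stand in for HMDB
  or METLIN coverage.
- The ORA universe defaults to the bundled database, which is the honest
  choice when the instrument's true detectable universe is unknown, but
  enrichment against a small universe is conservative.
- Missingness is treated as completely at random; intensity-dependent
  missingness would bias half-minimum imputation.
- The outlier Q-limit approximation needs several residual eigenvalues;
  the component cap mitigates but does not remove this.
- With $n \ll p$, in-fit classification metrics are uninformative;
  conclusions should rest on the cross-validated MCC and its permutation
  p-value.
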