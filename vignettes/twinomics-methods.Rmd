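---
title: "Models and design choices in twinomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in twinomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`twinomics` chains five estimators — growth-curve summarization, omics
preprocessing, mixed-model association scans, classical twin variance
decomposition and a residualized correlation network — and pairs each with a
generator whose parameters are fully known. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the methodology left room.

## The synthetic cohort

`generate_cohort()` creates MZ/DZ families and singletons. Defaults emulate
a Finnish adolescent twin sample: 106 MZ pairs, 164 DZ pairs and 111
singletons (651 individuals, 59% female), four survey waves at mean ages
11.4, 14.0, 17.6 and 22.4 years with family-level age jitter (sd 0.3, 0.1,
0.2, 0.7 years per wave — co-twins answer surveys together, so the jitter is
shared within a pair). MZ co-twins share sex; DZ co-twins' sexes are
independent, so roughly half of DZ pairs are opposite-sex. Singletons carry
`NA` zygosity and contribute no within-pair covariance anywhere downstream;
in the saturated twin fits they are grouped with the DZ likelihood, where
only their marginal (zygosity-free) density enters.

BMI waves follow a latent intercept/slope model,
`BMI_iw = η0_i + λ_w η1_i + ε_iw`. The slope loading is
`λ_w = Δt_w` (linear) or `ln(Δt_w + 1)` (logarithmic) with `Δt_w` the years
since the first reference age; the published loadings are never printed in
this literature, and this coding reproduces the observed magnitudes (a mean
log-scheme slope of ~2.2 corresponds to `2.2 × ln 12 ≈ 5.5` BMI units over
11 years). Growth factors follow an AE architecture (MZ genetic sharing 1,
DZ 0.5) with defaults chosen once from the published study conditions:
intercept mean 17.6, intercept sd 2.2, slope means 2.3 (M) / 2.0 (F), slope
sd 0.6, intercept heritability 0.72, slope heritability 0.63, wave residual
sd 0.5 BMI units. The intercept–slope correlation (default 0.3) is applied
to both the genetic and unique-environment component pairs; the implied
phenotypic correlation is `r(√(a₀²a₁²) + √(e₀²e₁²))`, which the
documentation states rather than hides. Heights come from sex-specific
reference stature curves with a stable individual deviation, and weights are
back-computed so `BMI = weight/height²` holds exactly.

`simulate_omics()` builds each feature as
`√h² · G + √c² · C + √e² · U` from a family-structured genetic component
`G`, a family-shared environmental component `C` and an individual component
`U`, so `h² + c² + e² = 1` holds exactly before batch effects. Couplings to
a target trait enter through `G` (weight `rA`) and `U` (weight `rE`),
giving the closed-form feature–trait correlation
`rA√(h²ₓh²ᵧ) + rE√(e²ₓe²ᵧ)` that the tests exploit as an oracle. The
default variance-fraction sampler emulates the published proteome: 80% of
features draw h² from Beta(2, 3.5) (mean ≈ 0.36) with c² = 0, and 20% are
purely shared-environmental with c² ~ U(0.19, 0.41) — matching the reported
mean protein heritability (35%) and the c² range of the CE-modelled
proteins. Batch effects are per-feature location shifts (sd 0.4 log2 units)
and scale factors (0.8–1.25) over 4 batches; missingness is
detection-limit-style left-censoring — within each batch the `k` lowest
values of a feature are censored, `k ~ Binomial(n_batch, q)` with
`q = 0.0086`, reproducing a dataset-wide missing fraction near 0.86% and
motivating minimum-value imputation. What the generator does *not* emulate:
non-normal feature distributions, age-heterogeneous waves beyond the jitter,
variant-level genotypes, and assay-specific artifacts; passing recovery
tests therefore demonstrates estimator correctness under the stated
architecture, not robustness to such real-data features.

`simulate_prs()` defines the score as `√r² · g + √(1−r²) · noise` with `g`
the standardized additive-genetic value of the target trait; `r² = 0.25` by
default, a realistic fidelity for current adiposity scores, with 10
independent nuisance PCs.

## Preprocessing

The stage order is fixed: log2 → exclusion list → missingness filter →
per-batch minimum imputation → batch adjustment → PCA outlier screen →
z-scaling. The missingness threshold is strict (a feature at exactly 10%
missing is retained). Batch adjustment is delegated to the parametric
empirical-Bayes ComBat implementation in `sva`, run on unscaled log2 values
with no covariates in the batch model; scaling comes last. On balanced
designs the location adjustment preserves feature means, but the scale
component perturbs them at the 1e-5 level, so the invariant is asserted at
1e-4. The outlier rule is per-component (|score| > 5 sd on PC1 or PC2), not
a joint Mahalanobis distance. Scaling uses the sample (n−1) standard
deviation. The 16-protein depletion-kit list ships as a plain-text fixture
and is applied by feature id before filtering.

## Latent growth curve model

`fit_lgcm()` maximizes the full-information likelihood over each
individual's observed-wave pattern, with mean structure
`μ_iw = α0 + λ_w α1 + β_age(age_iw − ref_w) (+ sex terms)` and covariance
`ΛΨΛ' + Θ`. Age adjustment uses a single shared coefficient across waves.
Sex adjustment acts on the growth-factor means only (not their variances):
under the `auto` rule a sex effect is retained iff its Wald p-value is below
0.05. Optimization is quasi-Newton on an unconstrained parameterization
(Cholesky of Ψ, log residual variances) with the residual variances floored
at 1e-4 BMI² so exactly rank-2 (noise-free) data stays on a bounded
likelihood surface; convergence requires a vanishing gradient on the free
parameters. Fit indices compare against a same-mean-structure saturated
model and an independence baseline; `N` in the RMSEA denominator is the
number of individuals, and the 90% CI inverts the noncentral chi-square.
When both time bases fit well `select_scheme()` prefers the linear one
(simpler interpretation); the published rule only specifies the converse
case. Factor scores use the regression (empirical-Bayes) method; the score
method was not named in the source literature. Robust standard errors are
the sandwich `H⁻¹(Σ_f g_f g_f')H⁻¹` with family-summed per-individual
scores obtained by central differences.

## Mixed-model association scans

The random structure operationalizes "a zygosity indicator and the family
identifier" as two nested variance components: a family intercept shared by
co-twins plus a second intercept shared only within MZ pairs (non-MZ
individuals get private levels). This is the reading that lets MZ pairs be
more correlated than DZ pairs — the evident purpose — whereas a two-level
zygosity-group intercept would be statistically near-degenerate. Because
families have at most two members, each pair is whitened by its
sum/difference contrasts with closed-form eigenvalues, the residual variance
is profiled out, and REML optimizes only the two variance ratios (bounded at
zero; boundary estimates are flagged). With no pairs, or no MZ pairs, the
unidentifiable components are fixed at zero. The Satterthwaite denominator
uses the gradient of the contrast variance in the variance components
(central differences, relative step 1e-6) and the inverse observed REML
information of the non-boundary components; in the i.i.d. limit the df
reduce to n − p. The implementation agrees with `lmerTest` to ~6 significant
digits on shared designs, and the test suite keeps that cross-check.
Outcomes and features are z-scored before fitting, the BMI intercept is a
mandatory covariate when the outcome is the BMI slope, Bonferroni m is the
number of features in the scan (failed fits still count), and ties in the
output ordering break by feature id.

## Classical twin models

All twin fits share one FIML engine: observation vectors per pair (2 traits
× 2 twins at most), grouped by zygosity and missingness pattern, with the
mean coefficients profiled out by GLS at every variance-parameter value.
Incomplete pairs contribute their marginal likelihood. Saturated models are
fitted per zygosity with exchangeable twin order and a common variance;
their correlations equal double-entry Pearson correlations when no
covariates are present, which the tests assert. The model-family rule is
`rDZ/rMZ > 0.5 → {ACE, AE, CE, E}`, otherwise `{AE}` — the published text
states the ratio in both orientations in different sentences; the
biometrically coherent reading (rDZ above half rMZ suggests shared
environment) is implemented and the conflicting phrasing treated as a typo.
Univariate components are parameterized directly as unbounded variances so
negative A or C estimates are attainable; E is kept positive by a box
constraint. Profile-likelihood CIs (χ²₁ 95% cutoff, bisection to 1e-4 on
the fraction scale, the single remaining free variance re-optimized in
closed 1-D) are provided for the AE and CE standardized components; the ACE
model falls back to delta-method CIs, flagged as such. The bivariate AE
model Cholesky-parameterizes both 2×2 blocks, so they are positive
semidefinite and |rA|, |rE| ≤ 1 at the ML point, and the identity
`rPh = rA√(h₁²h₂²) + rE√(e₁²e₂²)` holds to machine precision. Bivariate
rA/rE CIs are delta-method on the Fisher-z scale: profiling a correlation
inside a Cholesky block is ill-conditioned near |r| = 1, and the
delta-method fallback is the sanctioned alternative. Fits restart from a
deterministic ladder of scaled starting values before declaring
non-convergence, keeping seeded runs reproducible.

## Network and PRS stages

Scores are residualized on the 10 genetic PCs (plus platform indicators when
present) by OLS and z-scaled; orthogonality is exact by least squares.
Lipoprotein blocks are reduced by PCA with each component oriented so its
largest-magnitude loading is positive. Network nodes are residualized on 8
covariates (BMI slope, BMI intercept, BMI at sampling, age, age², sex,
sex×age, sex×age²). Edges are Pearson correlations on pairwise-complete
samples with t-transform p-values at n − 2 df — the residualization's lost
degrees of freedom are not further subtracted, a slight anticonservatism
noted here — and Bonferroni m equals the number of node pairs (300 for 25
nodes), recorded in the output since the published analysis does not state
its m.

## Problem sizes and verification

The test suite and `scripts/acceptance.R` use recovery simulations at the
study's own sizes: 200 replicates of 106 MZ + 164 DZ complete pairs for the
univariate (h² = 0.72 and 0.63) and bivariate (rE = 0.44) twin recoveries,
200 cohorts of 651 clustered individuals for the mixed-model effect
(0.46 sd/sd), 2 000 replicates for the Satterthwaite type-I calibration,
and up to 20 000 pairs for the Falconer moment oracle. Monte-Carlo
tolerances follow from the per-replicate sampling variability (for example,
the per-replicate sd of ĥ² at 270 pairs is ≈ 0.036, so the mean of 200
replicates is determined to ≈ 0.0025). For the bivariate recovery the
generating univariate structures are h² = 0.72 (the published BMI value)
and h² = 0.35 with rA = 0.29 (the published protein average and mean
absolute genetic correlation), chosen once; the protein-specific values are
not printed in the source literature. The mixed-model recovery generates
the outcome structurally (`y = 0.46·x + noise` with family-structured
noise independent of `x`) rather than as a joint correlation, because with
jointly family-correlated traits the co-twin's feature value is informative
and the conditional (mixed-model) estimand would differ from the marginal
correlation.

## Known limitations

No dominance (ADE) or sex-limitation twin models; no quadratic or spline
growth bases; no multi-group LGCM; Gaussian generators only; network edges
are marginal correlations, not partial correlations; and the empirical-Bayes
batch adjustment assumes the parametric prior forms of the ComBat family.
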