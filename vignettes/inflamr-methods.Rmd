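---
title: "Methods: dose-response, specificity and Mendelian randomisation for inflammation and mental health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response, specificity and Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflamr)
```

# The scientific problem

Circulating C-reactive protein (CRP) is elevated in people with depression
and anxiety, but cross-sectional association cannot distinguish causation
from confounding (adiposity, smoking, deprivation all raise both CRP and
symptom burden), from reverse causation, or from selection effects in
volunteer cohorts. `inflamr` implements the three complementary analyses
used to interrogate such an association in a biobank-scale cohort:

1. **Quantile dose-response** — CRP quintiles/deciles against PHQ-9 and
   GAD-7 symptom scores and probable diagnoses, with floating absolute
   risks, trend, quadratic and sex-interaction tests, and an
   inverse-probability-weighted (IPW) sensitivity analysis for
   outcome-dependent participation in the symptom survey.
2. **Disorder specificity** — joint (bivariate probit or bivariate
   Gaussian) modelling of depression and anxiety with a likelihood-ratio
   test of equality of the CRP coefficients, plus mutual adjustment of
   each disorder for the other.
3. **Mendelian randomisation (MR)** — one- and two-sample
   inverse-variance weighted (IVW) estimation using cis instruments in
   the *CRP* and *IL6R* gene regions, with Cochran's Q heterogeneity
   diagnostics and IPW-corrected SNP-outcome associations.

Because individual-level biobank data are access-controlled, the package
ships a synthetic cohort generator whose causal structure matches the
hypothesised biology (IL-6 activity drives CRP; either IL-6 or CRP may
affect symptom liability; participation in the symptom survey depends on
the symptoms themselves). Every estimator is validated against this
generator's known truth and against closed-form or quadrature oracles.

# The synthetic cohort generator

The generative chain is

genotypes → IL-6 activity → log-CRP → symptom liabilities → integer
scores → selection flag,

with independent Hardy–Weinberg biallelic dosages (no linkage
disequilibrium; MR instruments are conventionally LD-pruned), a shared
standard-normal latent confounder `u`, and observed covariates (age, sex,
BMI, smoking, alcohol, physical activity, ethnicity, Townsend deprivation
index, diabetes, cardiovascular disease) drawn from simple parametric
families whose marginals resemble a large mid-life population cohort.
The BMI gradient across CRP quintiles emerges from the BMI→CRP loading
rather than by construction.

Key scales and defaults:

* **IL-6 activity** is a unit-variance latent; IL6R-region SNPs add
  `gamma_il6r = (0.12, 0.10, 0.08)` per allele.
* **log-CRP** is normal with median 1.15 mg/L and SD ≈ 1.05 on the log
  scale (matching the reported median and interquartile range); CRP-region
  SNPs add `alpha_crp = (0.20, 0.15, 0.12, 0.10)` per allele; IL-6
  activity contributes `delta_il6_to_crp` (see the scale normalisation
  below).
* **Symptom liabilities** are unit-variance latents: causal terms
  (`theta_il6_*` per SD of IL-6 activity, `theta_crp_*` per unit log-CRP)
  plus confounder and covariate loadings plus correlated residuals. The
  residual variance is set per cohort so the marginal liability variance
  is exactly 1, which keeps the score link calibrated whatever the causal
  parameters.
* **Score link**: each score is negative binomial with log-mean linear in
  the liability, truncated at the scale maximum (27 for PHQ-9, 21 for
  GAD-7). Symptom sum-scores are right-skewed counts with many zeros; a
  truncated NB with dispersion 20 reproduces the published mean, SD and
  tail. The link parameters (depression: intercept 0.492, slope 1.041;
  anxiety: 0.065, 1.227) were calibrated once by simulation so the
  default cohort reproduces mean scores 2.76 and 2.15, probable-diagnosis
  prevalences 5.5% and 4.4% (score ≥ 10), and — with residual liability
  correlation 0.90 — an observed score correlation of 0.68.
* **Selection** is logistic in the two symptom scores, age, sex and TDI
  (defaults `-0.12` and `-0.05` per score point, intercept 0.45, ~55%
  selected). Because the scores themselves enter the participation model,
  conditioning on `selected == 1` opens a collider path between CRP and
  the outcomes; the published IPW participation model is in an
  unavailable supplement, so this minimal outcome-dependent form is a
  stand-in, exposed in the configuration.
* **Sex effects** are multiplicative modifiers on the four theta
  parameters. The default is `(1, 1)`: sex modification off, so that
  interaction tests are correctly null-calibrated under defaults.
  Stronger female effects are simulated by setting the multipliers
  explicitly.

## The scale normalisation behind the MR estimand

Score-based analyses model `log(score + 1)`. A causal effect `theta` on
the liability scale translates to the analysis scale through the link
slope `k = dE[log(score+1)]/dL`, computed exactly by Gauss–Hermite
quadrature and the Stein identity (`score_link_slope()`; ≈ 0.62 for the
depression link). The IL-6→CRP loading default `delta_il6_to_crp = 0.619`
is set equal to that slope, so the one-sample IVW estimand over IL6R
instruments — SNP effects on `log(score+1)` divided by SNP effects on
log-CRP — equals `theta_il6_dep` exactly. This is a units convention, not
a behavioural assumption: it makes the generator's causal parameters
directly interpretable as the quantities the MR stage estimates, and the
`TruthRecord` stores the implied analysis-scale estimands
(`truth$estimand`) for all four exposure-outcome pairs in any case.

## What the generator does not emulate

No linkage disequilibrium, imputation uncertainty, population
stratification or relatedness; no assay floor or acute-phase exclusions
(CRP values above 10 mg/L are neither truncated in simulation nor
excluded in analysis, since no such exclusion was specified); no missing
covariates; and the joint prevalence of the two probable diagnoses is
higher than in real data because the latent correlation required to
reproduce the score correlation of 0.68 through independent NB noise is
high (0.90). Passing tests therefore demonstrate correctness of the
estimators under the stated causal structure, not robustness to every
feature of real biobank data.

# Observational dose-response

CRP quantile groups are type-1 empirical quantiles of the analysis
sample, with ties at a cut point assigned to the lower group. Symptom
scores are analysed as `log(score + 1)` in linear regression and the
coefficients exponentiated to OR-style ratios — anti-logging a
coefficient is only meaningful for a log-scale response, and the exact
regression family behind published "ORs from linear models" is not
stated, so this interpretation is a package design decision. Probable
diagnoses (PHQ-9 ≥ 10, GAD-7 ≥ 10) use logistic regression. Adjustment
sets follow the conventional staged models: 1 unadjusted; 2 + age, sex,
BMI; 3 + smoking, alcohol, activity, ethnicity, TDI; 4 + diabetes and
cardiovascular disease, all as indicator sets, complete cases only.

**Floating absolute risks.** Given the covariance `V` of the `K-1`
reference-coded log-ORs, the floated variance of the reference is
estimated as the mean off-diagonal of `V` (the variance component every
contrast shares through the reference) and `lambda_k = V[k,k] -
lambda_0`. For compound-symmetric `V` this is exact, with
`Var(beta_i - beta_j) = lambda_i + lambda_j` recovered identically; an
optional least-squares refinement minimises the total squared error of
that identity over all pairs including the reference. The named technique
does not pin down an algorithm, so the package uses this exactly testable
estimator. Floated variances are floored at `1e-12` and the number of
floored entries recorded.

**Trend, linearity, sex interaction.** The trend OR uses the quantile
index as a continuous predictor; linearity is tested by a Wald test of a
squared log-CRP term; sex interaction by a sex × log-CRP product term,
with stratified fits reported alongside.

**IPW.** The participation model is logistic in covariates that include
the symptom scores; selected rows are weighted by `1/p_hat` (optionally
stabilised by the marginal selection fraction), probabilities floored at
`1e-3` with truncations counted, and all weighted fits use robust
(sandwich, HC0) standard errors because weighting invalidates
model-based variances.

# Disorder specificity

For the categorical outcomes the package maximises the exact bivariate
probit likelihood. Orthant probabilities come from a vectorised
implementation of the Genz (2004) 20-point Gauss–Legendre algorithm for
the bivariate normal CDF (`pbvnorm()`, absolute accuracy ~1e-14 across
the correlation range, validated in the test suite against 2-D numerical
integration); a vectorised CDF is what makes 400-replicate null
calibration of the test feasible. Optimisation is BFGS with analytic
gradients, started at the two univariate probit fits and `rho = 0`. The
latent correlation is parameterised as `0.999 * tanh(w)`, smooth and
bounded away from `|rho| = 1` so that degenerate, perfectly concordant
outcome pairs remain well behaved. Convergence requires a gradient
max-norm below `1e-3` relative to the log-likelihood magnitude (with one
automatic restart), otherwise an error carrying the diagnostics is
raised. Quasi-separation is detected at the univariate starts.

The specificity test compares the free model with one whose CRP
coefficient is shared between equations (covariates remain free):
`LR = 2(ll_free - ll_constrained)` on 1 df, with small negative values
clipped to zero. Probit coefficients are converted to ORs by the
conventional 1.6 scaling, `OR = exp(1.6 b)`.

A probit likelihood is undefined for continuous responses, and the exact
published construction for continuous outcomes is unknown, so the
"continuous" path is a bivariate Gaussian seemingly-unrelated regression
on the transformed scores: the free fit is equation-wise OLS with the MLE
residual covariance (exact, since the design matrices coincide); the
constrained fit is iterated feasible GLS, which converges to the
constrained MLE; the same LRT machinery applies. No attempt is made to
match any published per-unit probit ORs for continuous scores, whose
scaling is not described.

Mutual adjustment re-fits each disorder's CRP model adding the other
disorder's raw score as a covariate; a degenerate (constant) comorbid
score is dropped automatically, reproducing the unadjusted fit.

# Mendelian randomisation

Per-SNP associations are one regression per SNP of the (transformed)
variable on dosage, adjusted for age and sex by default (sex is dropped
within strata; genetic principal components are out of scope because the
simulator has no stratification). Monomorphic SNPs are dropped with a
log entry. IPW variants weight the selected rows and use sandwich
standard errors.

Harmonisation aligns outcome to exposure effect alleles: label swaps
negate the beta and complement the frequency; strand flips are resolved
by complementing; palindromic SNPs are aligned by effect-allele frequency
only when both frequencies lie outside (0.42, 0.58), otherwise dropped —
a convention, with flip/drop counts always reported.

The IVW estimate is the weighted regression of outcome on exposure betas
through the origin, equal to the `beta_x^2/se_y^2`-weighted mean of the
per-SNP Wald ratios (this identity is asserted to 1e-12 in the tests and
is the oracle for every IVW call). Wald-ratio variances are first order
(`se_y/|beta_x|`), appropriate for strong instruments. The fixed-effect
SE is the default — the published analyses do not state a random-effects
choice — with a multiplicative random-effects option inflating by
`max(1, sqrt(Q/(J-1)))`. Cochran's Q uses the same first-order weights
and a chi-squared reference on `J-1` df; with a single instrument the
estimate reduces to the Wald ratio and Q is reported missing with 0 df.
One-sample estimation on overlapping samples is permitted (as in the
design it mirrors); no winner's-curse correction is applied.

# Validation problem sizes

The test suite validates: simulator marginals at the reference cohort
size (n = 146,954); IVW against the closed form on fixed and random
instrument tables; Cochran's Q null calibration (2,000 replicates,
J = 5); bivariate-probit LRT size and chi-squared(1) null shape (400
replicates at n = 5,000); causal-effect recovery and CI coverage for the
IL-6 pathway (200 replicates at n = 50,000 with `theta_il6_dep = 0.3`);
and the collider-bias demonstration with IPW correction (200 replicates
at n = 20,000). These sizes give Monte-Carlo error comfortably inside
each acceptance band while keeping the default test run tractable on a
single CPU.

# Known limitations

* The generator's selection model is a minimal stand-in, not a
  reconstruction of any published participation model.
* The compound-symmetry floated-variance estimator is exact only when
  contrast covariances share a single reference component; the
  least-squares refinement relaxes but does not remove this.
* The continuous-outcome specificity analysis is a Gaussian SUR
  interpretation; other joint constructions are possible.
* First-order Wald-ratio variances understate uncertainty for weak
  instruments; the simulator's defaults give per-SNP F statistics well
  above 50, where the approximation is standard.
* `pbvnorm()` is accurate to ~1e-10 only for `|rho| <= 0.999`, which the
  probit parameterisation enforces.
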