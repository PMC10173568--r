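---
title: "Measuring parent-adolescent informant discrepancy with latent difference scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring parent-adolescent informant discrepancy with latent difference scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadlds)
```

## The problem

When a parent and an adolescent each fill in the same short behavioural
questionnaire about the adolescent — here an SDQ-style instrument with five
5-item subscales rated 0/1/2 — the two reports routinely disagree. The
*informant discrepancy* is scientifically interesting in its own right: in
general-population samples parents tend to report fewer difficulties and
more pro-social behaviour than adolescents report about themselves, and the
size of the gap varies with adolescent sex and with parental
characteristics such as psychological distress and education.

Comparing raw sum scores confounds three things: true disagreement,
measurement error, and items that simply work differently for the two
reporters (different wording, different connotations). `dyadlds` implements
the latent approach that separates them:

1. **Measurement-invariance testing** across reporters (configural →
   metric → scalar), with a capped *partial-invariance* rescue driven by
   modification indices, so that latent mean comparison rests on a majority
   of invariant items.
2. A **latent difference score (LDS)** model in which a second-order factor
   Δ carries the true parent-minus-self difference, free of measurement
   error.
3. **Conditional LDS** models in which both the self factor and Δ are
   regressed on a binary moderator, so the moderator's effect on the
   discrepancy is net of its effect on self-report.
4. **Inverse-probability weighting** for unit nonresponse, multiplied into
   an external survey weight, with sandwich standard errors under weighting
   and full-information ML (FIML) for item-level missingness.

## The model

All models are linear structural equation models with mean structure, in
the all-y LISREL form. With loadings $\Lambda$, intercepts $\nu$, residual
covariance $\Theta$, latent regressions $B$, latent disturbance covariance
$\Psi$ and latent intercepts $\alpha$:

$$\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T} \Lambda' + \Theta,
\qquad \mu(\theta) = \nu + \Lambda (I-B)^{-1} \alpha.$$

Estimation minimizes the normal-theory discrepancy
$F = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p +
(\bar m-\mu)'\Sigma^{-1}(\bar m-\mu)$ over (possibly weighted) sample
moments, or maximizes the casewise likelihood over each observation's
observed subset (FIML). Analytic gradients are used throughout; a
quasi-Newton optimizer (L-BFGS-B, variances bounded below at $10^{-6}$)
is followed by a Newton polish so that closed-form identities hold to
machine precision.

**The LDS parameterization.** For one construct, five self items measure
$\eta_S$ and five parent items measure $\eta_P$. The parent factor's mean
and disturbance are fixed to zero, and two unit paths are imposed:
$\eta_P = 1\cdot\eta_S + 1\cdot\Delta$. The second-order factor $\Delta$
then *is* the latent parent-minus-self difference, with free mean
$\alpha_\Delta$, variance $\phi_\Delta$, and covariance
$\sigma_{S\Delta}$ with the self factor. Positive $\alpha_\Delta$ means
parents rate higher. This is an exact reparameterization of the two-factor
CFA with free means: the package tests that the two models have identical
likelihoods and that $\hat\alpha_\Delta$ equals the difference of the CFA
factor means to $10^{-6}$.

**Identification.** Marker convention: the first item of each subscale has
its loading fixed to 1 and intercept fixed to 0; latent means are free
(they must be, for the LDS mean to be estimable). The motivating analysis
does not state its identification convention; output headers flag ours.
One visible consequence: a first item's intercept can never be freed in the
partial-invariance search, so non-invariance patterns that involve first
items (which did occur in the motivating study for two subscales) cannot be
emulated exactly under this convention.

**The chi-square convention** is $T = \sum_g n_g F_g$ with $n_g$ the group
size (not $n_g - 1$). CFI and RMSEA use the standard definitions against an
independence baseline with free means and variances;
$\mathrm{RMSEA} = \sqrt{\max(T - df, 0)/(df\,N)}\cdot\sqrt{G}$ with the
$\sqrt G$ multiplier only in two-independent-groups mode. SRMR is computed
over correlation-metric covariance residuals only (one of several published
variants; mean residuals are excluded), averaged across groups with $n_g$
weights.

## The invariance ladder and partial-invariance search

The ladder compares configural (no cross-reporter equality), metric
(loadings tied) and scalar (loadings and intercepts tied) models. A step
is accepted iff the loss of fit against the previously accepted step
satisfies both $\Delta\mathrm{CFI} \le 0.010$ and
$\Delta\mathrm{RMSEA} \le 0.015$; $\Delta$SRMR is reported but not used
for acceptance. On failure, the search frees the equality-constrained
parameter of the failing class (loadings at the metric step, intercepts at
the scalar step) with the largest modification index, refits, and
re-evaluates — capped at two of the five items per parameter class, so a
majority of indicators stays invariant; ties break by item order; markers
are never candidates. The rule is criteria-driven, not MI-threshold-driven:
the largest-MI parameter is freed even when its MI is below 3.84.

Modification indices are univariate score (Lagrange-multiplier) tests with
*expected* (Fisher) information, each candidate evaluated in its own
one-parameter extension of the fitted model. Splitting an equality label
changes what the remaining label ties, so candidates must not share an
extended parameter space — a subtle error mode we test against explicitly.
The package requires MI to agree with the actual refit chi-square drop
within 10% whenever MI > 3.84.

Two dyad treatments are available. The default, *joint-dyad* mode keeps
both reporter factors in one model over the paired sample, respecting the
within-dyad dependence the LDS model needs. *Two-group* mode treats the
reporters as independent samples (the description "multi-group CFA" in the
motivating text is ambiguous; both are provided). Same-item residual
covariances across reporters are off by default, available behind a flag.

## Conditional models and standardization

Each binary moderator (adolescent sex, male = 1 with female the reference;
parental high distress; parental high education) is analysed in its own
model, never jointly: the covariate enters as a pseudo-latent variable
equal to the observed column, with regressions onto $\eta_S$ and $\Delta$.
Per-level discrepancy estimates are the nonlinear combinations
$\alpha_\Delta/\sqrt{\phi_\Delta}$ (reference level) and
$(\alpha_\Delta+\beta_\Delta)/\sqrt{\phi_\Delta}$ (other level), with
95% CIs by the delta method on the full combination including the
square-root denominator; the package checks these against a 2000-draw
parametric bootstrap (endpoints within 10%).

Standardization choices (the source analysis does not print formulas):

* the standardized discrepancy mean is $\alpha_\Delta/\sqrt{\phi_\Delta}$
  (an alternative divisor — the total parent-factor SD — is available);
* the standardized self/discrepancy covariance is
  $\sigma_{S\Delta}/(\sqrt{\phi_\Delta}\sqrt{\psi_S})$;
* covariate effects are standardized by the respective factor's
  *reference-level* (disturbance) SD. This is deliberately not the usual
  `std.all` (which multiplies by the covariate SD and divides by the
  marginal factor SD), so conditional effect sizes here are larger in
  magnitude than `std.all` values and should not be compared to them
  directly.

Significance stars follow the conventional two-sided Wald thresholds
\*p < .05, \*\*p < .01, \*\*\*p < .001.

## Weights and missing data

Unit nonresponse (a dyad failing to provide usable questionnaires) is
handled by inverse probability weighting: a logistic propensity model for
the complete-case flag on fully observed covariates, fitted by IRLS
(tolerance $10^{-8}$); IPW = 1/propensity among complete cases, capped at
the 99th percentile of the untrimmed IPW distribution (the source is
silent on trimming; capping stabilizes pseudo-ML estimation and is
configurable); the product with the external survey weight is rescaled to
mean 1 over analysed cases, which leaves point estimates invariant and
keeps sandwich SEs on an interpretable scale. With informative weights,
SEs come from the sandwich estimator $A^{-1} B A^{-1}$ with $A$ the
observed information and $B$ the outer product of weighted casewise
scores. Item-level missingness is handled by FIML (casewise likelihoods
grouped by missingness pattern), used in the sensitivity rerun because
weighting and FIML are not combined.

## The synthetic cohort: what it emulates, and what a green test means

Since the study's real cohort data are registration-gated, every stage is
exercised on a synthetic dyad generator with known latent truth. Per
construct and dyad, $(\eta_S, \Delta)$ are bivariate normal with
configured moments, $\eta_P = \eta_S + \Delta$ by construction, and each
item is a thresholded normal: $y^* = \nu + \lambda\eta + \varepsilon$,
with the observed rating $\#\{\tau < y^*\}$, default thresholds
$(0.5, 1.5)$ so the rating is the rounded continuous response clipped to
0–2.

Defaults are fixed once and constitute the stated world:

* discrepancy moments per construct (standardized mean −0.898 / −0.424 /
  −0.195 / +0.506; variances 0.097 / 0.081 / 0.105 / 0.066; standardized
  covariances −0.49 / −0.58 / −0.35 / −0.48) match the magnitudes reported
  for the four analysed SDQ subscales;
* self-item intercepts equal the published self-report item means; the
  latent self SD is 0.45 and residual SDs 0.45 in the 0–2 item metric,
  giving item SDs around 0.6, in the realistic range;
* covariate effects enter the latent means *centered* (x minus its design
  prevalence), so configured means remain the marginal moments; effect
  sizes are converted from the published conditional tables to the raw
  latent metric, with male = 1, high distress = 1, high education = 1;
* parental distress is generated through a 6-item 0–4 screen from a
  distress factor, thresholds calibrated once so that the ≥ 5 cutoff
  classifies 34.6% as high-distress; education prevalence 0.563 (NVQ ≥ 4),
  male prevalence 0.507;
* unit nonresponse follows a logistic model on sex, distress and
  education, intercept calibrated to 64.6% marginal completeness
  (6947/10757); item-level MCAR 2% among complete cases;
* default measurement non-invariance shifts one parent loading and one or
  two parent intercepts per construct, emulating the freed-item pattern
  (moved off marker items where the published pattern conflicts with the
  identification convention);
* `calibrate_to_moments()` can instead match any item mean/SD targets
  (e.g. the packaged table of published item moments) by inverting the
  thresholded-normal marginal per item.

**The deliberate mismatch.** Items are generated ordinally but analysed as
continuous, mirroring the ML treatment of 3-point items in the motivating
analysis. This makes the linear SEM *misspecified by design*, and the
estimator converges to a pseudo-true projection rather than the generating
latent values. Measured at n = 400k, the pseudo-true standardized
discrepancy means are −0.846 / −0.459 / −0.186 / +0.530 against generating
values −0.898 / −0.424 / −0.195 / +0.506: coarsening biases of 0.01–0.05
SD units. Two consequences, both verified rather than hidden:

* truth-centered recovery assertions at 3-Monte-Carlo-SE precision fail
  for three of four constructs, and 95% CI coverage of the *generating*
  value drops to the mid-80s; the acceptance tests state these as written
  and they stay red. A companion test shows the estimator is centered on
  the pseudo-true value within 3 MC SE — the machinery is consistent for
  its estimand;
* a latent intercept offset also perturbs an item's local slope (the
  derivative of the threshold response), most strongly for floor-bound
  items; the invariance ladder therefore sometimes attributes an intercept
  offset to the metric (loading) step. With continuous indicators the
  offset is detected as an intercept essentially always.

The generator also does not mimic the cohort's sampling design: a single
log-normal survey-weight column (mean 1) stands in for the real design
weights, and no clustering or stratification is emulated — so a green test
establishes correctness of the estimators under the stated world, not
design-based variance properties.

## Numerical choices

* Optimizer: L-BFGS-B, relative tolerance $10^{-8}$, max 500 iterations,
  up to 3 jittered restarts on nonconvergence, then a guarded Newton
  polish (2 steps) using a finite-difference Hessian of the analytic
  gradient.
* Residual and latent variances are bounded below at $10^{-6}$; estimates
  at the bound trigger a Heywood warning, and a discrepancy variance at
  the bound suppresses the standardized mean (division by ~0).
* A singular sample covariance (e.g. literally duplicated reporter
  columns) drops the constant $\log|S|$ term with a warning so estimation
  can proceed; absolute fit statistics are then only relative.
* Equality constraints are implemented by parameter pooling (shared
  labels), never penalties; ties in the partial search break by item
  order.
* All randomness flows from a single seed; identical seeds give
  byte-identical generated CSVs and study bundles.

## Known limitations

* No categorical-indicator (WLSMV/probit) estimation — deliberately, since
  the approach being implemented treats 3-point items as continuous; the
  coarsening analysis above quantifies the cost.
* No robust (scaled) chi-square corrections; plain sandwich SEs stand in
  under weighting.
* No design-based variance estimation (strata/clusters), no longitudinal
  LDS, no joint five-factor modelling beyond the univariate CFA gates, no
  clinical banding of sum scores.
* The hyperactivity-inattention subscale is expected to fail the
  univariate CFA gate on realistic data (it is not unidimensional in older
  adolescents) and is excluded from defaults.
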