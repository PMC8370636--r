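---
title: "Methods: random-intercept panel models, MAP factor scores, and clustered-bootstrap mediation for polygenic-score analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-intercept panel models and clustered-bootstrap mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The analytic problem

`twinpath` implements a complete pipeline for studying how two polygenic
scores (PGSs) — one trained on regular smoking, one on years of education —
relate to facets of academic adjustment in adolescence (grade point
average, self/parent- and teacher-rated academic motivation, disciplinary
problems, cigarettes per day) and, through them, to educational attainment
in adulthood.  The design has three statistical stages:

1. **Random-intercept panel models (RI-PMs)** split each repeatedly
   measured trait into a time-invariant stable component (the random
   intercept) and occasion-specific states linked by autoregressive
   paths.  Conditional versions regress the stable component on one or
   both PGSs plus control covariates (sex, five ancestry principal
   components).
2. **Maximum a posteriori (MAP) factor scores** extract each person's
   stable-trait estimate from an unconditional RI-PM, so that
3. a **recursive path (mediation) model** can regress adult attainment on
   the PGSs directly and through the five stable traits, with
   family-clustered nonparametric percentile bootstrap confidence
   intervals.

Because the underlying cohort data are not public, the package includes a
first-class synthetic twin-cohort generator whose defaults are calibrated
to the cohort's published descriptive statistics (see
`reference_targets()`), so every stage of the pipeline runs and can be
validated end to end without external data.

## The random-intercept panel model

For occasions $t = 1, \dots, T$ (ages 11/14/17 for the academic traits,
14/17/21/24 for cigarettes per day):

$$y_t = \mu_t + \eta + r_t, \qquad
  r_1 = e_1, \quad r_t = \rho_{t-1} r_{t-1} + e_t,$$

with $\eta \sim N(\Gamma'x,\ \psi)$ independent of the occasion process
and $e_t \sim N(0, \theta_t)$.  All factor loadings are fixed to 1;
occasion intercepts $\mu_t$ vary freely; the intercept factor has mean
zero (unconditional model) and free variance.  The autoregressive paths
between the occasion residual factors matter: omitting them pushes the
lag-correlation they generate into $\hat\psi$, biasing the stable-trait
variance upward (a directional property verified in the test suite).

The implied covariance follows the recursion
$\mathrm{Var}(r_t) = \rho_{t-1}^2\mathrm{Var}(r_{t-1}) + \theta_t$,
$\mathrm{Cov}(r_s, r_t) = \prod_{u=s}^{t-1}\rho_u \cdot \mathrm{Var}(r_s)$,
plus a constant $\mathrm{Var}(\eta)$ in every cell (`implied_moments()`).
With $T = 3$ the covariance structure is just-identified
($2T$ parameters against $T(T+1)/2$ moments), so a complete-data fit
reproduces the sample moments exactly; `ripm_params_from_moments()`
exposes this solve directly.

### Estimation

`fit_ripm()` maximizes the casewise full-information maximum-likelihood
(FIML) criterion: each person contributes the multivariate-normal
log-likelihood of whatever subset of occasions they were observed at,
grouped by missingness pattern for speed.  Numerical choices:

* variances are optimized on the log scale, which keeps the implied
  covariance positive definite throughout the search;
* starting values come from the exact moment solve of the available-case
  covariance (falling back to a compound-symmetry start if that fails);
* the quasi-Newton (BFGS) search uses a $10^{-6}$ finite-difference step
  and an objective tolerance of $10^{-14}$, followed by a second pass
  with a numerically estimated Hessian for the parameter covariance.
  Convergence is reported together with the per-case gradient norm;
* predictors are treated as fixed regressors (the likelihood is
  conditional on $x$), matching the single-outcome-block structure of the
  conditional model: covariates point at the random intercept only, not
  at the occasion residuals.

Standardized coefficients divide by the model-implied stable-trait SD,
$\sqrt{\Gamma' S_x \Gamma + \psi}$, and multiply by the sample predictor
SD.  Family clustering is deliberately ignored in point estimation — each
twin contributes a likelihood term — and inference is delegated entirely
to the family-clustered bootstrap, mirroring the two-level strategy of
the reference analysis.

## MAP factor scores

Under normality the posterior of $\eta$ given a person's observed
occasions is normal, so the posterior mean and mode coincide and have the
closed form

$$\hat\eta = \Gamma'x + \psi\, \mathbf{1}'\Sigma_{obs}^{-1}
  (y_{obs} - \mu_{obs} - \mathbf{1}\Gamma'x),$$

implemented in `map_scores()` without any optimization.  With a single
occasion and $\psi = \theta$ this is the familiar shrinkage factor
$\psi/(\psi+\theta) = 1/2$.  `score_reliability()` reports
$\mathrm{Var}(\hat\eta)/\psi = \psi\,\mathbf{1}'\Sigma_{obs}^{-1}\mathbf{1}$
for any observation pattern; it is monotone in the pattern and reaches 1
as $\theta \to 0$.

Two-step caveat: downstream regressions use scores, not the latent trait.
For any external variable $z$ uncorrelated with the occasion noise,
$\mathrm{cor}(\hat\eta, z) = \sqrt{R}\,\mathrm{cor}(\eta, z)$ where $R$ is
the score reliability, and score-score correlations attenuate by
$\sqrt{R_iR_j}$.  This is a property of the two-step design itself (the
reference analysis shares it); the package does not correct for it, and
the mediation stage therefore uses scores from *unconditional* fits so
that predictor effects are not double-counted through the score's mean
component.

## Mediation model and inference

`fit_path_model()` fits the fully recursive system — every exogenous
variable to every mediator and to the outcome, every mediator to the
outcome — by equation-wise least squares, which is the maximum-likelihood
solution for this just-identified structure.  Mediator residual
covariances are estimated from the equation residuals (the
seemingly-unrelated structure with identical regressor sets makes this
exact).  Indirect effects are coefficient products $a_ib_i$; on complete
data the identity $\text{total} = c' + \sum_i a_ib_i$ holds at machine
precision against the mediator-free regression, and the test suite
asserts it at `1e-13`.

`cluster_bootstrap()` resamples whole families with replacement to the
original family count — both twins always move together — refits the
statistic set per draw, and reports empirical 2.5/97.5 percentile
intervals.  Draws on which the statistic fails are dropped and counted;
more than 5% failures aborts.  The significance rule
(`flag_significance()`) is a conjunction: the 95% percentile interval
must exclude zero *and* the p-value must be below .005.  The auxiliary
p-value's construction is not pinned down by the reference analysis; the
package computes a two-sided normal approximation from the bootstrap SE,
keeping the percentile interval as the primary criterion.
`decompose_effects()` suppresses the proportion mediated whenever
$|\text{total}| \le .01$ because the ratio is unstable near zero.

## The synthetic twin cohort

`cohort_config()` + `simulate_cohort()` generate the study conditions the
models assume.  Defaults emulate the published cohort: 1881 same-sex twin
pairs (64.1% MZ; 66.7% recruited at age 11, the rest at age 17).

* **Polygenic scores.**  Standardized bivariate normal with
  within-person correlation $-.23$; MZ co-twins share scores exactly, DZ
  correlate $.50$ (expected sib sharing — not stated in the reference,
  chosen as the biometric default), with cross-twin-cross-trait
  correlation $.5 \times (-.23)$.
* **Stable traits.**  Each trait's standardized stable component is
  $\eta_i = \gamma_{s i}\,\mathrm{PGS}_s + \gamma_{e i}\,\mathrm{PGS}_e +
  \delta_i$ with the published two-predictor path coefficients as
  $\gamma$ defaults and $\delta$ covariances solved so the total
  $\eta$-$\eta$ correlations match the published correlation matrix.
  $\delta$ is decomposed ACE-style (additive-genetic fraction .40 shared
  $\times 1$ in MZ / $\times .5$ in DZ pairs, shared environment .30,
  the rest unique — the twin-meta-analysis figures for educational
  attainment), purely so family clustering is realistic for the
  bootstrap; the reference analysis fits no biometric model.
* **Occasion structure.**  Per trait, $(\psi, \theta_t, \rho_t)$ are the
  exact moment solve of the published occasion SDs and stabilities, so
  population means/SDs/autocorrelations match the published table by
  construction.
* **Informants.**  Two-informant traits emit reports $y \pm d$, so the
  informant mean reproduces the trait value exactly while the informant
  correlation hits its published target (.79 GPA, .51 motivation);
  teacher counts are 1-3 per child (P = .25/.45/.30, giving ~75% with at
  least two) with within-person-centered noise and an assumed .70
  inter-teacher correlation (not published).  Composites are therefore
  Gaussian and not hard-clipped to instrument ranges: clipping would
  shift the published means/SDs the generator is required to reproduce.
  The bounded item-level coding paths (`compose_gpa()`,
  `code_discipline_items()`, ...) are exercised on bounded fixtures in
  the unit tests instead.
* **Cigarettes per day.**  A latent stable+AR process is standardized
  per occasion and mapped through
  $\mathrm{clamp}(\mathrm{round}(m_t + k_t z), 0, 6)$ with $(m_t, k_t)$
  solved per occasion so the coded variable's population mean and SD
  equal the published values; raw cigarettes/day are emitted as
  per-category representative counts so `code_cigarettes()` round-trips
  the category.  The latent autoregression (.45 per step) was chosen
  once to land the coded stability near the published mean
  autocorrelation and is not otherwise calibrated.
* **Attainment.**  A latent liability combines the five stable traits
  (published outcome paths), the two PGSs (published direct effects), an
  age effect and Gaussian noise, and is thresholded.  The published
  category shares sum to 94.7%, not 100; thresholds are placed at the
  cumulative shares of categories 1–5, which preserves those five shares
  exactly and leaves the residual mass in the top category.  Because
  categorisation attenuates correlations by
  $\lambda = \mathrm{cor}(L, \mathrm{cat}(L)) = 0.961$ (closed form from
  the threshold quantiles), the latent age coefficient is set to
  $.27/\lambda$ so the *observed* age-attainment correlation is .27.
  The latent $R^2$ defaults to $.36/\lambda^2$ for the same reason.
* **Missingness** (`apply_missingness()`) is missing-completely-at-random:
  older-cohort participants have no age-11/14 assessments by design;
  whole visits are lost at the pair level (retention .914 at 14 and .863
  at 17 for the younger cohort; .717 at 21 and .866 at 24 for everyone —
  the last two derived from published Ns); teacher reports are available
  for .699/.720/.598 of retained visits; attainment is missing with
  probability .079.

What the generator does *not* emulate: bounded/ordinal item support for
the academic composites, genotype-level structure (no LD, no real
ancestry confounding — the principal components are pure noise
covariates that exercise the plumbing), informant-specific variance
shares beyond what the published inter-informant correlations pin down,
and non-random dropout.  Passing tests therefore show that the
*estimators* behave correctly under the published moment structure, not
that they are robust to violations real data might add (informative
missingness, floor effects in cigarettes and discipline, ordinal
measurement).

## Other implementation decisions on points the design left open

* Motivation items are taken to be on a 1–4 response scale (six-item
  sums range 6–24, bracketing the published means of ~19.6–20.9);
  composites are per-informant sums averaged across informants.
* "Present if reported by either informant" for discipline items is the
  elementwise maximum, which honours either-report presence while
  keeping the 0/1/2 grading.
* The discipline CFA treats the 0/1/2 items as continuous (linear ML,
  factor variance fixed to 1, regression-method scores recomputed per
  missingness pattern).  With two indicators the model is identified by
  an equal-loadings constraint ($\lambda = \sqrt{r_{12}}$).  A fit is
  flagged *degenerate* when fewer than two loadings are salient
  ($|\lambda| \ge .3$): on uncorrelated items, ML factor analysis
  concentrates on a single variable rather than shrinking all loadings.
* Cigarettes-per-day bins fix only the endpoints (0 = none, 6 = 20+/day);
  the interior defaults are <1, 1–5, 6–10, 11–15, 16–19 and are
  config-overridable.
* Educational attainment is age-residualized by ordinary least squares
  on the observed records, and the unstandardized residual feeds the
  path model.
* "Mean autocorrelation" in the reporting helpers averages *lag-1*
  correlations only; this is the only definition that reproduces all
  four published per-trait values from the published occasion
  correlations.  Printed renderings use two-decimal round-half-up.

## Problem sizes used by the test suite

The suite favours a few deep, parameterised checks over many shallow
ones.  Simulation-backed properties run at sizes chosen to keep Monte
Carlo error well below the asserted tolerances: moment checks at 4,000
families (~4 MC SEs with a twin design effect of 2), FIML recovery at
2,000 families over 100 replications (mean absolute bias below .01),
bootstrap coverage over 200 replications of 500 families with 200 draws
per replicate, and the null likelihood-ratio calibration over 150
replications with a Kolmogorov–Smirnov check against $\chi^2_1$.  The
acceptance script simulates the default 1,881-family cohort for the
descriptive anchors and larger cohorts (20,000/50,000 persons) for the
categorical share and PGS-correlation targets.

## Known limitations

* Factor-score regressions are not corrected for score unreliability;
  standardized mediation paths are attenuated by design (documented
  above), exactly as in the two-step reference strategy.
* The FIML fitter covers the single-trait RI-PM family it is specified
  for, not general SEM (no free loadings, no multiple latent factors per
  trait, no ordinal indicators).
* MCAR missingness is the default; the generator has no
  outcome-dependent dropout mechanism, so FIML's MAR robustness is only
  exercised under MCAR.
* The attainment liability is linear-normal before thresholding;
  real-world category distributions need not arise this way.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- cohort_config(n_families = 800)
dat <- apply_missingness(simulate_cohort(cfg, seed = 1))
w <- panel_wide(dat)

## stage 1: unconditional RI-PM per trait, e.g. GPA
fit_gpa <- fit_ripm(w, ripm_spec(c("gpa_11", "gpa_14", "gpa_17")))

## stage 2: MAP scores from the unconditional fit
w$ri_gpa <- map_scores(fit_gpa, w)$score

## stage 3: mediation with clustered bootstrap (sketch, one mediator)
w$ea_residual <- NA
obs <- !is.na(w$ea_category)
w$ea_residual[obs] <- residualize_attainment(
  data.frame(ea_category = w$ea_category,
             age_at_report = w$age_at_report))$ea_residual[obs]
spec <- path_spec(c("pgs_smoking", "pgs_edu", "sex_num",
                    paste0("pc", 1:5)),
                  "ri_gpa", "ea_residual")
w$sex_num <- as.numeric(w$sex == "F")
fit <- fit_path_model(w, spec)
bt <- cluster_bootstrap(
  w, function(d) {
    f <- fit_path_model(d, spec)
    c(direct = unname(f$cprime_std["pgs_smoking"]),
      indirect = unname(f$indirect_std["pgs_smoking", "ri_gpa"]))
  }, n_draws = 1000, seed = 2)
decompose_effects(fit)
```
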