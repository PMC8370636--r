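# twinpath

Polygenic scores (PGSs) for smoking and for educational attainment each
predict academic outcomes, but they index partly distinct genetic
influences: broadly, behavioral disinhibition versus cognitive/academic
skill acquisition.  `twinpath` implements the full analytic pipeline for
studying both scores together across adolescence and into adulthood:

* **Random-intercept panel models (RI-PMs)** for traits measured at ages
  11/14/17 (GPA, self/parent- and teacher-rated academic motivation,
  disciplinary problems) and 14/17/21/24 (cigarettes per day):
  `y_t = mu_t + eta + r_t` with `r_t = rho_{t-1} r_{t-1} + e_t`, where
  the random intercept `eta` is the stable trait and the autoregressive
  residual factors absorb occasion-specific variance.  Conditional
  models regress `eta` on one or two PGSs plus controls
  (`eta = Gamma'x + zeta`), estimated by casewise full-information
  maximum likelihood (FIML) so partially observed cases contribute.
* **MAP factor scores** — the closed-form posterior mean
  `Gamma'x + psi 1' Sigma_obs^{-1} (y_obs - mu_obs - 1 Gamma'x)` — for
  each stable trait.
* A **recursive mediation model** (2 PGSs + controls → 5 stable traits →
  age-adjusted educational attainment) with direct/indirect/total effect
  decomposition (`total = c' + sum a_i b_i`, exact on complete data) and
  **family-clustered nonparametric percentile bootstrap** confidence
  intervals; a coefficient is flagged significant only if its 95%
  interval excludes 0 *and* p < .005.
* **Measurement constructors** for the analysis variables
  (multi-informant composites, either-informant discipline coding with a
  one-factor ML CFA, 0–6 cigarettes-per-day binning, age-residualized
  attainment) and minimal **PGS scoring** from a dosage matrix and
  weight table.
* A **synthetic twin-cohort generator** (`cohort_config()`,
  `simulate_cohort()`, `apply_missingness()`) whose defaults reproduce
  the published descriptive statistics of the cohort the models were
  designed for — MZ/DZ polygenic-score sharing, stable+AR trait
  structure, informant noise, categorical cigarettes and attainment,
  cohort- and attrition-based missingness — so the whole pipeline runs
  with no external data.  See `reference_targets()` for the calibration
  anchors and the methods vignette (`vignettes/twinpath-methods.Rmd`)
  for how each default was derived.

## Worked example

Simulate a 1,500-family cohort, fit the two-PGS conditional RI-PM for
GPA, then run a single-mediator mediation of attainment through the GPA
stable trait:

```r
library(twinpath)
cfg <- cohort_config(n_families = 1500)
dat <- apply_missingness(simulate_cohort(cfg, seed = 1))
w <- panel_wide(dat)
w$sex_num <- as.numeric(w$sex == "F")
ctrl <- c("sex_num", paste0("pc", 1:5))

fit2 <- fit_ripm(w, ripm_spec(c("gpa_11", "gpa_14", "gpa_17"),
                              c("pgs_smoking", "pgs_edu", ctrl)))
round(fit2$standardized, 3)
#> pgs_smoking     pgs_edu     sex_num         pc1         pc2         pc3
#>      -0.066       0.250      -0.036       0.061       0.028       0.024
#>         pc4         pc5
#>      -0.023       0.028
```

The standardized paths estimate the PGS effects on the *stable* part of
GPA (generating values −.09 and .22; the controls are pure-noise
covariates).  Scores from the unconditional fit then feed the path
model:

```r
fit0 <- fit_ripm(w, ripm_spec(c("gpa_11", "gpa_14", "gpa_17")))
w$ri_gpa <- map_scores(fit0, w)$score
w$ea_residual <- residualize_attainment(
  data.frame(ea_category = w$ea_category,
             age_at_report = w$age_at_report))$ea_residual

spec <- path_spec(c("pgs_smoking", "pgs_edu", ctrl),
                  "ri_gpa", "ea_residual")
fit <- fit_path_model(w, spec)
decompose_effects(fit)[1:2, ]
#>     exogenous direct indirect_ri_gpa  total prop_mediated
#> 1 pgs_smoking -0.138         -0.0145 -0.153        0.0949
#> 2     pgs_edu  0.177          0.0497  0.227        0.2188

bt <- cluster_bootstrap(w, function(d) {
  f <- fit_path_model(d, spec)
  c(indirect_smoking = unname(f$indirect_std["pgs_smoking", "ri_gpa"]))
}, n_draws = 200, seed = 2)
bt
#> Clustered percentile bootstrap: 200 draws (0 failed), cluster = family_id
#>                  estimate     se   lower   upper
#> indirect_smoking  -0.0145 0.0065 -0.0267 -0.0014
flag_significance(bt$estimate, bt$ci[1, ], se = bt$se)
#> [1] FALSE
```

The smoking PGS's indirect effect through the GPA stable trait is small
and negative: its percentile interval excludes zero, but the p-value
fails the < .005 part of the conjunction rule, so it is not flagged.
With one mediator only ~10% of the smoking-PGS total effect is mediated;
the full five-mediator model transmits much more.

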