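test_that("implied moments follow the stable-trait + AR(1) recursion", {
  ## rho = 0: compound symmetry
  cs <- implied_moments(ripm_params(c(0, 0, 0), 1, c(1, 1, 1), c(0, 0)))
  expect_equal(cs$cov, matrix(1, 3, 3) + diag(3))
  ## closed-form recursion at rho = .5
  m <- implied_moments(ripm_params(c(0, 0, 0), 1, c(1, 1, 1),
                                   c(0.5, 0.5)))
  expect_equal(diag(m$cov), c(2, 2.25, 2.3125))
  expect_equal(m$cov[1, 2], 1.5)
  expect_equal(m$cov[1, 3], 1.25)
  expect_equal(m$cov[2, 3], 1.625)
  ## theta -> 0 limit: everything collapses to the stable trait
  lim <- implied_moments(ripm_params(c(0, 0, 0), 1, rep(1e-10, 3),
                                     c(0.3, 0.8)))
  expect_equal(lim$cov, matrix(1, 3, 3), tolerance = 1e-8)
  ## Monte-Carlo oracle: simulate the process directly
  Y <- simulate_ripm_process(300000, mu = c(1, 2, 3), psi = 0.8,
                             theta = c(0.5, 0.7, 0.4),
                             rho = c(0.6, 0.3), seed = 42)
  m2 <- implied_moments(ripm_params(c(1, 2, 3), 0.8, c(0.5, 0.7, 0.4),
                                    c(0.6, 0.3)))
  expect_equal(colMeans(Y), m2$mean, tolerance = 0.02)
  expect_equal(cov(Y), m2$cov, tolerance = 0.02)
})

test_that("implied covariance stays positive definite over randomized admissible parameters", {
  set.seed(99)
  for (i in 1:200) {
    T <- sample(2:5, 1)
    p <- ripm_params(rnorm(T), exp(rnorm(1)), exp(rnorm(T)),
                     runif(T - 1, -1.5, 1.5))
    ev <- eigen(implied_moments(p)$cov, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("a just-identified complete-data fit reproduces the sample moments", {
  d <- simulate_conditional_panel(1500, c(0, 0), seed = 21)
  f <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3")))
  expect_true(f$convergence$converged)
  Y <- as.matrix(d[, c("y1", "y2", "y3")])
  S_ml <- cov(Y) * (nrow(Y) - 1) / nrow(Y)
  im <- implied_moments(f$params)
  expect_equal(im$mean, colMeans(Y), tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(im$cov, S_ml, tolerance = 1e-6, ignore_attr = TRUE)
  ## FIML on complete data equals the complete-data ML (moment) solution
  mm <- ripm_params_from_moments(S_ml, colMeans(Y))
  expect_equal(f$params$psi, mm$psi, tolerance = 1e-5)
  expect_equal(f$params$theta, mm$theta, tolerance = 1e-5)
  expect_equal(f$params$rho, mm$rho, tolerance = 1e-5)
})

test_that("conditional FIML recovers standardized effects from correlated predictors", {
  d <- simulate_conditional_panel(8000, c(-0.13, 0.32), seed = 31)
  f <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), c("x1", "x2")))
  expect_true(f$convergence$converged)
  ## absolute tolerance ~ 3 Monte-Carlo SEs of a standardized
  ## latent-trait effect at this n
  expect_lt(max(abs(unname(f$standardized) - c(-0.13, 0.32))), 0.05)
  ## null predictor: standardized effect near zero
  d$noise <- rnorm(nrow(d))
  f0 <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), "noise"))
  expect_lt(abs(f0$standardized), 3 / sqrt(nrow(d)) * 1.5)
})

test_that("FIML uses partially observed cases and matches truth under MCAR", {
  set.seed(41)
  d <- simulate_conditional_panel(6000, c(-0.13, 0.32), seed = 41)
  for (j in 1:3)
    d[[paste0("y", j)]][runif(6000) < 0.3] <- NA
  dropped <- rowSums(!is.na(d[, c("y1", "y2", "y3")])) == 0
  f <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), c("x1", "x2")))
  expect_equal(f$n_used, sum(!dropped))
  expect_equal(unname(f$standardized), c(-0.13, 0.32), tolerance = 0.05)
  expect_equal(f$params$rho, c(0.5, 0.5), tolerance = 0.1)
})

test_that("standardized coefficients are invariant to affine rescaling", {
  d <- simulate_conditional_panel(2000, c(-0.2, 0.3), seed = 51)
  f1 <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), c("x1", "x2")))
  d2 <- d
  d2$x1 <- 10 * d$x1 + 5
  for (j in 1:3) d2[[paste0("y", j)]] <- 3 * d[[paste0("y", j)]] - 7
  f2 <- fit_ripm(d2, ripm_spec(c("y1", "y2", "y3"), c("x1", "x2")))
  expect_equal(f1$standardized, f2$standardized, tolerance = 1e-4)
})

test_that("omitting autoregressive paths inflates the stable-trait variance", {
  d <- simulate_conditional_panel(8000, c(0, 0), theta = c(1, 1, 1),
                                  rho = c(0.6, 0.6), seed = 61)
  f_ar <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3")))
  f_no <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"),
                                autoregressive = FALSE))
  expect_equal(f_ar$params$psi, 1, tolerance = 0.1)
  expect_gt(f_no$params$psi, f_ar$params$psi + 0.2)
})

test_that("cross-sectional regression matches the normal-equations oracle", {
  d <- data.frame(y = c(1.2, -0.5, 0.3, 2.2, -1.0, 0.6),
                  a = c(1, 0, -1, 2, 0.5, -0.2),
                  b = c(0.3, 1.1, -0.4, 0.8, -1.2, 0.1))
  f <- fit_crosssection(d, "y", c("a", "b"))
  X <- cbind(1, d$a, d$b)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(f$standardized),
               unname(beta[2:3] * c(sd(d$a), sd(d$b)) / sd(d$y)),
               tolerance = 1e-10)
  ## outcome identical to the predictor: standardized coefficient 1
  d$z <- d$a
  expect_equal(unname(fit_crosssection(d, "z", "a")$standardized), 1)
  ## pure-noise outcome at large n: coefficient near 0
  set.seed(7)
  big <- data.frame(y = rnorm(10000), x = rnorm(10000))
  expect_lt(abs(fit_crosssection(big, "y", "x")$standardized), 0.04)
  ## rank deficiency is reported with the offending column
  d$dup <- d$a
  expect_error(fit_crosssection(d, "y", c("a", "dup")), "dup")
})

test_that("tidy export lists every parameter with standardized values and CIs", {
  d <- simulate_conditional_panel(800, c(-0.2, 0.3), seed = 81)
  d$family_id <- rep(seq_len(400), each = 2)
  f <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), c("x1", "x2")))
  bt <- cluster_bootstrap(d, function(dd)
    fit_ripm(dd, ripm_spec(c("y1", "y2", "y3"),
                           c("x1", "x2")))$params$gamma |>
      setNames(c("gamma_x1", "gamma_x2")),
    n_draws = 30, seed = 3)
  td <- ripm_tidy(f, ci = bt)
  expect_equal(nrow(td), 3 + 1 + 3 + 2 + 2)
  g <- td[td$parameter == "gamma_x2", ]
  expect_false(is.na(g$standardized))
  expect_true(g$ci_lower < g$estimate & g$estimate < g$ci_upper)
  expect_true(all(is.na(td$ci_lower[td$parameter == "psi"])))
})

test_that("likelihood-ratio test has the right null behaviour and power", {
  d <- simulate_conditional_panel(1200, c(0.3, 0), seed = 71)
  full <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), c("x1", "x2")))
  red <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3")))
  lt <- lr_test(full, red)
  expect_equal(lt$df, 2)
  expect_lt(lt$p_value, 1e-10)   # strong true effect
  expect_gt(lt$delta_chi2, 0)
  ## identical models
  same <- lr_test(full, full)
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p_value, 1)
  expect_error(lr_test(red, full), "fewer")
})

test_that("null-simulation Delta chi-square follows its reference distribution", {
  ## true extra coefficient zero: rejection rate at alpha = .05 within
  ## binomial error, and the statistic matches chi-square(1) quantiles
  reps <- 150
  stats <- p_vals <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- simulate_conditional_panel(250, c(0, 0), seed = 1000 + i)
    full <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3"), "x1"))
    red <- fit_ripm(d, ripm_spec(c("y1", "y2", "y3")))
    lt <- lr_test(full, red)
    stats[i] <- lt$delta_chi2
    p_vals[i] <- lt$p_value
  }
  rej <- mean(p_vals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
  expect_gt(stats::ks.test(stats, stats::pchisq, df = 1)$p.value, 0.01)
})
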