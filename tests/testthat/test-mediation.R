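test_that("single-mediator path model matches the closed-form solution exactly", {
  R <- matrix(c(1, 0.5, 0.4,
                0.5, 1, 0.5,
                0.4, 0.5, 1), 3, 3,
              dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
  d <- make_exact_corr_data(R, n = 400, seed = 2)
  f <- fit_path_model(d, path_spec("x", "m", "y"))
  expect_equal(unname(f$a_std["x", "m"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(f$b_std["m"]), 0.4, tolerance = 1e-10)
  expect_equal(unname(f$cprime_std["x"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(f$indirect_std["x", "m"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(f$total_std["x"]), 0.4, tolerance = 1e-10)
})

test_that("effect decomposition identity holds at machine precision", {
  set.seed(31)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n)
  m1 <- 0.4 * x1 - 0.2 * x2 + rnorm(n)
  m2 <- -0.3 * x1 + 0.1 * x2 + rnorm(n)
  y <- 0.5 * m1 - 0.25 * m2 + 0.15 * x1 + rnorm(n)
  d <- data.frame(x1, x2, m1, m2, y)
  f <- fit_path_model(d, path_spec(c("x1", "x2"), c("m1", "m2"), "y"))
  ## total effect equals the mediator-free regression coefficient exactly
  red <- coef(lm(y ~ x1 + x2, d))[c("x1", "x2")]
  expect_equal(unname(f$total), unname(red), tolerance = 1e-12)
  expect_equal(f$total, f$cprime + rowSums(f$indirect),
               tolerance = 1e-14)
  ## standardized invariance to affine rescaling
  d2 <- d
  d2$x1 <- 4 * d$x1 - 1
  d2$m1 <- 0.5 * d$m1 + 3
  d2$y <- 2 * d$y + 10
  f2 <- fit_path_model(d2, path_spec(c("x1", "x2"), c("m1", "m2"), "y"))
  expect_equal(f$a_std, f2$a_std, tolerance = 1e-10)
  expect_equal(f$total_std, f2$total_std, tolerance = 1e-10)
})

test_that("null mediators give near-zero indirect effects with covering CIs", {
  set.seed(32)
  n <- 2000
  d <- data.frame(family_id = rep(1:(n / 2), each = 2),
                  x = rnorm(n))
  d$m <- rnorm(n)              # no a-path, no b-path
  d$y <- 0.3 * d$x + rnorm(n)
  f <- fit_path_model(d, path_spec("x", "m", "y"))
  expect_lt(abs(f$indirect_std["x", "m"]), 0.03)
  bt <- cluster_bootstrap(
    d, function(dd) c(ind = unname(
      fit_path_model(dd, path_spec("x", "m", "y"))$indirect_std[1, 1])),
    n_draws = 200, seed = 9)
  expect_lte(bt$ci["ind", "lower"], 0)
  expect_gte(bt$ci["ind", "upper"], 0)
})

test_that("decompose_effects reports proportion mediated with the stability guard", {
  f <- list(indirect_std = matrix(-0.08, 1, 1,
                                  dimnames = list("pgs", "m")),
            cprime_std = c(pgs = -0.07),
            total_indirect_std = c(pgs = -0.08),
            total_std = c(pgs = -0.15))
  class(f) <- "path_fit"
  out <- decompose_effects(f)
  expect_equal(out$prop_mediated, -0.08 / -0.15, tolerance = 1e-12)
  expect_equal(round(out$prop_mediated, 3), 0.533)
  f$total_std <- c(pgs = 0.005)
  expect_true(is.na(decompose_effects(f)$prop_mediated))
  f$total_indirect_std <- c(pgs = 0)
  f$total_std <- c(pgs = 0.2)
  expect_equal(decompose_effects(f)$prop_mediated, 0)
})

test_that("clustered bootstrap is deterministic, keeps pairs together, and handles failures", {
  set.seed(33)
  n <- 400
  d <- data.frame(family_id = rep(1:(n / 2), each = 2), x = rnorm(n))
  s <- function(dd) c(m = mean(dd$x))
  b1 <- cluster_bootstrap(d, s, n_draws = 100, seed = 4)
  b2 <- cluster_bootstrap(d, s, n_draws = 100, seed = 4)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$ci, b2$ci)
  ## constant statistic: zero-width interval
  b0 <- cluster_bootstrap(d, function(dd) c(k = 1), n_draws = 50,
                          seed = 1)
  expect_equal(unname(b0$ci["k", "lower"]), 1)
  expect_equal(unname(b0$ci["k", "upper"]), 1)
  ## pairs resampled together: every draw has an even count of each family
  cnt <- cluster_bootstrap(
    d, function(dd) c(frac_even = mean(table(dd$family_id) %% 2 == 0)),
    n_draws = 20, seed = 2)
  expect_true(all(cnt$draws[, "frac_even"] == 1))
  ## > 5% failures abort
  flaky <- function(dd) if (runif(1) < 0.5) stop("boom") else c(m = 1)
  expect_error(cluster_bootstrap(d, flaky, n_draws = 100, seed = 5),
               "failed")
})

test_that("bootstrap confidence intervals shrink roughly as 1/sqrt(families)", {
  set.seed(34)
  width <- function(n_fam, seed) {
    d <- data.frame(family_id = rep(seq_len(n_fam), each = 2))
    d$x <- rnorm(nrow(d))
    d$m <- 0.4 * d$x + rnorm(nrow(d))
    d$y <- 0.4 * d$m + rnorm(nrow(d))
    b <- cluster_bootstrap(
      d, function(dd) c(ab = unname(
        fit_path_model(dd, path_spec("x", "m", "y"))$indirect_std[1, 1])),
      n_draws = 150, seed = seed)
    unname(diff(b$ci["ab", ]))
  }
  w1 <- stats::median(vapply(1:4, function(s) width(300, s), 0))
  w2 <- stats::median(vapply(1:4, function(s) width(1200, s), 0))
  ## quadrupling families should halve the width, within tolerance
  expect_gt(w1 / w2, 1.5)
  expect_lt(w1 / w2, 2.7)
})

test_that("the two-part significance rule is a strict conjunction", {
  expect_true(flag_significance(0.32, c(0.26, 0.40), p = 1e-8))
  expect_false(flag_significance(-0.03, c(-0.08, 0.02), p = 1e-8))
  expect_false(flag_significance(0.32, c(0.26, 0.40), p = 0.01))
  ## p from the bootstrap SE when not supplied
  expect_true(flag_significance(0.32, c(0.26, 0.40), se = 0.04))
  expect_false(flag_significance(0.08, c(0.01, 0.15), se = 0.04))
  expect_error(flag_significance(0.1, c(0.2, 0.1)), "ordered")
  expect_error(flag_significance(0.1, c(0.0, 0.2)), "`p` or `se`")
})

test_that("adding the polygenic scores to the outcome equation is detected by the LR test", {
  ## simulation calibrated to the published path coefficients
  set.seed(35)
  n <- 3000
  tg <- reference_targets()
  Sp <- matrix(c(1, -0.23, -0.23, 1), 2)
  X <- matrix(rnorm(n * 2), n, 2) %*% chol(Sp)
  colnames(X) <- c("pgs_smoking", "pgs_edu")
  G <- cbind(tg$path_truths$beta[tg$path_truths$pgs == "pgs_smoking" &
                                   grepl("^ri_", tg$path_truths$target)],
             tg$path_truths$beta[tg$path_truths$pgs == "pgs_edu" &
                                   grepl("^ri_", tg$path_truths$target)])
  M <- X %*% t(G) + matrix(rnorm(n * 5), n, 5) %*%
    diag(sqrt(1 - rowSums((G %*% t(chol(Sp)))^2)))
  colnames(M) <- paste0("m", 1:5)
  b <- tg$path_truths$beta[tg$path_truths$pgs == "outcome"]
  cpr <- c(-0.07, 0.11)
  y <- drop(M %*% b) + drop(X %*% cpr) + rnorm(n, sd = 0.75)
  d <- data.frame(X, M, y = y, family_id = rep(1:(n / 2), each = 2))
  full <- fit_path_model(d, path_spec(c("pgs_smoking", "pgs_edu"),
                                      paste0("m", 1:5), "y"))
  ## reduced outcome equation: mediators only
  red <- fit_path_model(d, path_spec(character(0) , paste0("m", 1:5),
                                     "y"))
  expect_error(path_spec(character(0), "m", "m"))
  lt <- lr_test(full, red)
  expect_equal(lt$df, 2)
  expect_lt(lt$p_value, 0.001)
  expect_gt(full$r_squared, red$r_squared)
})
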