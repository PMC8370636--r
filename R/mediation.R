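#' Specify the mediation path model
#'
#' A fully recursive system: every exogenous variable predicts every
#' mediator and the outcome; every mediator predicts the outcome.
#' Residual covariances among the mediators are implied by the
#' seemingly-unrelated structure (identical regressor sets) and estimated
#' from the equation residuals.
#'
#' @param exogenous Character vector of exogenous predictor columns
#'   (polygenic scores and control covariates).
#' @param mediators Character vector of mediator columns (random-intercept
#'   factor scores).
#' @param outcome Single outcome column (age-adjusted attainment).
#' @return Object of class `path_spec`.
#' @export
path_spec <- function(exogenous, mediators, outcome) {
  if (length(outcome) != 1) stop("exactly one outcome variable")
  if (length(intersect(mediators, c(exogenous, outcome))))
    stop("mediator set must be disjoint from exogenous and outcome")
  structure(list(exogenous = exogenous, mediators = mediators,
                 outcome = outcome), class = "path_spec")
}

#' Fit the mediation path model
#'
#' Fits each endogenous equation by least squares (for this fully
#' recursive, just-identified structure the equation-wise least-squares
#' solution is the maximum-likelihood path fit): every mediator regressed
#' on the exogenous set (a-paths), and the outcome regressed on the
#' exogenous set and all mediators (b-paths and direct effects c').
#' Indirect effects are the products `a_i * b_i`; the total effect of an
#' exogenous variable is `c' + sum_i a_i b_i`, which on complete data
#' equals the coefficient from the regression omitting the mediators
#' exactly.  Standardized coefficients use sample SDs.
#'
#' @param data Data frame containing all model columns; complete cases are
#'   used.
#' @param spec A [path_spec()].
#' @return Object of class `path_fit` with raw and standardized a/b/c'
#'   paths, per-mediator and total indirect effects, total effects,
#'   outcome `r_squared`, mediator residual covariance, and bookkeeping
#'   used by [lr_test()] and [cluster_bootstrap()].
#' @export
fit_path_model <- function(data, spec) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- c(spec$exogenous, spec$mediators, spec$outcome)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, vars]), vars]
  n <- nrow(d)
  n_par <- length(spec$exogenous) + length(spec$mediators) + 1
  if (n < 5 * n_par)
    stop("need at least 5 cases per parameter (", 5 * n_par, "), got ", n)

  Xe <- cbind(`(Intercept)` = 1,
              as.matrix(d[, spec$exogenous, drop = FALSE]))
  qe <- qr(Xe)
  if (qe$rank < ncol(Xe))
    stop("collinear exogenous design; offending columns: ",
         paste(colnames(Xe)[qe$pivot[-seq_len(qe$rank)]], collapse = ", "))
  M <- as.matrix(d[, spec$mediators, drop = FALSE])
  y <- d[[spec$outcome]]

  A <- qr.coef(qe, M)                      # (1+p) x m
  A <- matrix(A, nrow = ncol(Xe),
              dimnames = list(colnames(Xe), spec$mediators))
  med_resid <- M - Xe %*% A
  Xf <- cbind(Xe, M)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf))
    stop("collinear full design; offending columns: ",
         paste(colnames(Xf)[qf$pivot[-seq_len(qf$rank)]], collapse = ", "))
  bf <- setNames(qr.coef(qf, y), colnames(Xf))
  out_resid <- y - drop(Xf %*% bf)

  a <- A[-1, , drop = FALSE]               # p x m
  b <- bf[spec$mediators]
  cprime <- bf[spec$exogenous]
  indirect <- sweep(a, 2, b, "*")          # p x m
  total_indirect <- rowSums(indirect)
  total <- cprime + total_indirect

  sx <- apply(d[, spec$exogenous, drop = FALSE], 2, sd)
  sm <- apply(M, 2, sd)
  sy <- sd(y)
  a_std <- a * (sx %o% (1 / sm))
  b_std <- b * sm / sy
  cprime_std <- cprime * sx / sy
  indirect_std <- sweep(a_std, 2, b_std, "*")
  total_indirect_std <- rowSums(indirect_std)
  total_std <- cprime_std + total_indirect_std
  rss <- sum(out_resid^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)

  structure(list(
    spec = spec, n_used = n,
    a = a, b = b, cprime = cprime,
    indirect = indirect, total_indirect = total_indirect, total = total,
    a_std = a_std, b_std = b_std, cprime_std = cprime_std,
    indirect_std = indirect_std,
    total_indirect_std = total_indirect_std, total_std = total_std,
    r_squared = r2, outcome_rss = rss, outcome_coef = bf,
    mediator_resid_cov = cov(med_resid),
    sds = list(x = sx, m = sm, y = sy)),
    class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Recursive path model: ", length(x$spec$exogenous),
      " exogenous -> ", length(x$spec$mediators), " mediators -> ",
      x$spec$outcome, " (n = ", x$n_used, ")\n", sep = "")
  cat("  outcome R^2:", round(x$r_squared, 3), "\n")
  cat("  standardized direct effects:\n")
  print(round(x$cprime_std, 3))
  cat("  standardized total indirect effects:\n")
  print(round(x$total_indirect_std, 3))
  invisible(x)
}

#' Direct / indirect / total effect decomposition
#'
#' Per exogenous variable: the direct effect, each mediator-specific
#' indirect effect, the total indirect effect, the total effect, and the
#' proportion mediated (total indirect over total), which is suppressed
#' when `|total| <= 0.01` because the ratio is unstable near zero.
#'
#' @param fit A [fit_path_model()] result.
#' @param standardized Report standardized effects (default `TRUE`).
#' @return Tibble with one row per exogenous variable.
#' @export
decompose_effects <- function(fit, standardized = TRUE) {
  stopifnot(inherits(fit, "path_fit"))
  if (standardized) {
    ind <- fit$indirect_std; dir <- fit$cprime_std
    ti <- fit$total_indirect_std; tot <- fit$total_std
  } else {
    ind <- fit$indirect; dir <- fit$cprime
    ti <- fit$total_indirect; tot <- fit$total
  }
  pm <- ifelse(abs(tot) > 0.01, ti / tot, NA_real_)
  out <- tibble::tibble(exogenous = rownames(ind), direct = unname(dir))
  for (m in colnames(ind)) out[[paste0("indirect_", m)]] <- ind[, m]
  out$total_indirect <- unname(ti)
  out$total <- unname(tot)
  out$prop_mediated <- unname(pm)
  out
}

#' Family-clustered nonparametric percentile bootstrap
#'
#' Resamples whole clusters (families) with replacement to the original
#' cluster count — both twins of a pair always move together — recomputes
#' the statistic set on each draw, and returns empirical 2.5/97.5
#' percentile 95% confidence intervals.  Draws on which the statistic
#' fails are dropped and counted; more than 5% failures aborts.
#' Deterministic given `seed`.
#'
#' @param data Data frame with a cluster key column.
#' @param statistic Function `data -> named numeric vector`.
#' @param n_draws Number of bootstrap draws (the reference analysis uses
#'   1000).
#' @param seed Integer seed.
#' @param cluster Name of the cluster key column (default `family_id`).
#' @param level Confidence level (default 0.95).
#' @return Object of class `boot_result`: `estimate` (statistic on the
#'   original data), `draws` (n_draws x k matrix), `ci` (k x 2), `se`
#'   (bootstrap SDs), `n_draws`, `n_failed`, `seed`, `cluster`.
#' @export
cluster_bootstrap <- function(data, statistic, n_draws = 1000L,
                              seed = 1L, cluster = "family_id",
                              level = 0.95) {
  if (!cluster %in% names(data)) stop("cluster key '", cluster,
                                      "' not found")
  if (n_draws < 1) stop("n_draws must be >= 1")
  est <- statistic(data)
  k <- length(est)
  rows_by_fam <- split(seq_len(nrow(data)), data[[cluster]])
  Fn <- length(rows_by_fam)
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, k,
                  dimnames = list(NULL, names(est)))
  n_failed <- 0L
  for (b in seq_len(n_draws)) {
    fams <- sample.int(Fn, Fn, replace = TRUE)
    idx <- unlist(rows_by_fam[fams], use.names = FALSE)
    val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val) || length(val) != k || anyNA(val)) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- val
    }
  }
  if (n_failed > 0.05 * n_draws)
    stop("bootstrap aborted: ", n_failed, " of ", n_draws,
         " draws failed (> 5%)")
  ok <- stats::complete.cases(draws)
  alpha <- (1 - level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  se <- apply(draws[ok, , drop = FALSE], 2, sd)
  structure(list(estimate = est, draws = draws, ci = ci, se = se,
                 n_draws = n_draws, n_failed = n_failed, seed = seed,
                 cluster = cluster, level = level),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat("Clustered percentile bootstrap: ", x$n_draws, " draws (",
      x$n_failed, " failed), cluster = ", x$cluster, "\n", sep = "")
  tab <- cbind(estimate = x$estimate, se = x$se, x$ci)
  print(round(tab, 4))
  invisible(x)
}

#' Two-part significance rule
#'
#' A parameter is flagged statistically significant only if the bootstrap
#' 95% confidence interval excludes 0 AND its p-value is below .005.  When
#' `p` is not supplied it is computed as a two-sided normal approximation
#' from the estimate and the bootstrap SE (the percentile-interval
#' criterion remains primary).
#'
#' @param estimate Point estimate.
#' @param ci Length-2 ordered interval `c(lower, upper)`.
#' @param p Optional p-value; computed from `se` if omitted.
#' @param se Bootstrap standard error (needed when `p` is omitted).
#' @param p_threshold Significance threshold for the p-value part
#'   (default 0.005).
#' @return Logical flag (with attribute `p` carrying the p-value used).
#' @export
flag_significance <- function(estimate, ci, p = NULL, se = NULL,
                              p_threshold = 0.005) {
  if (length(ci) != 2 || ci[1] > ci[2])
    stop("`ci` must be an ordered (lower, upper) pair")
  if (is.null(p)) {
    if (is.null(se)) stop("either `p` or `se` must be supplied")
    p <- 2 * pnorm(-abs(estimate / se))
  }
  flag <- (ci[1] > 0 || ci[2] < 0) && p < p_threshold
  attr(flag, "p") <- p
  flag
}
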