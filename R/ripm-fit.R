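#' Specify a random-intercept panel model
#'
#' @param occasions Character vector (length >= 2) of outcome column names
#'   in temporal order, e.g. `c("gpa_11", "gpa_14", "gpa_17")`.
#' @param predictors Character vector of predictor column names for the
#'   conditional model (empty for the unconditional model).
#' @param autoregressive Include autoregressive paths between successive
#'   occasion residual factors (default `TRUE`; `FALSE` fixes them to 0).
#' @return An object of class `ripm_spec`.
#' @seealso [fit_ripm()]
#' @export
ripm_spec <- function(occasions, predictors = character(),
                      autoregressive = TRUE) {
  occasions <- as.character(occasions)
  predictors <- as.character(predictors)
  if (length(occasions) < 2) stop("at least 2 occasions required")
  if (anyDuplicated(c(occasions, predictors)))
    stop("occasion/predictor names must be unique")
  structure(list(occasions = occasions, predictors = predictors,
                 autoregressive = isTRUE(autoregressive)),
            class = "ripm_spec")
}

#' Fit a random-intercept panel model by full-information maximum likelihood
#'
#' Estimates the RI-PM of [ripm_params()] by casewise FIML: each person
#' contributes the multivariate-normal log-likelihood of their observed
#' occasions (grouped by missingness pattern for speed), so all partially
#' observed cases are used.  Variance parameters are optimized on the log
#' scale, which keeps the implied covariance positive definite throughout
#' the search.  Starting values are method-of-moments (moment solve of the
#' available-case covariance).  In conditional models the random intercept
#' is regressed on the predictors (`eta = Gamma'x + zeta`), the likelihood
#' is conditional on x, and persons with incomplete predictors are
#' dropped.
#'
#' Standardized coefficients divide by the model-implied stable-trait SD,
#' `sqrt(Gamma' S_x Gamma + psi)`, and multiply by the sample predictor SD.
#'
#' @param data Wide data frame holding the occasion and predictor columns.
#' @param spec An [ripm_spec()].
#' @return Object of class `ripm_fit`: `params` ([ripm_params()]),
#'   `standardized` (named vector, conditional models), `loglik`, `n_used`,
#'   `convergence` (list: `converged`, `grad_norm`, `optim_status`),
#'   `vcov` (parameter covariance, internal parameterization), `se_gamma`,
#'   `spec`, `predictor_moments`.
#' @export
fit_ripm <- function(data, spec) {
  stopifnot(inherits(spec, "ripm_spec"))
  Y <- as.matrix(data[, spec$occasions, drop = FALSE])
  T <- ncol(Y)
  p <- length(spec$predictors)
  X <- if (p) as.matrix(data[, spec$predictors, drop = FALSE]) else NULL
  keep <- rowSums(!is.na(Y)) >= 1
  if (p) keep <- keep & complete.cases(X)
  Y <- Y[keep, , drop = FALSE]
  if (p) X <- X[keep, , drop = FALSE]
  n <- nrow(Y)
  if (n < T + p + 2) stop("too few usable cases (", n, ")")

  ar <- spec$autoregressive
  n_rho <- if (ar) T - 1 else 0

  ## method-of-moments starts from available-case moments; with the AR
  ## structure the exact moment solve is a near-optimal start (and the
  ## exact MLE for complete unconditional data)
  mu0 <- colMeans(Y, na.rm = TRUE)
  S0 <- cov(Y, use = "pairwise.complete.obs") * (n - 1) / n
  S0[!is.finite(S0)] <- 0
  psi0 <- max(mean(S0[upper.tri(S0)]), 1e-3)
  theta0 <- pmax(diag(S0) - psi0, 0.05 * diag(S0))
  rho0 <- rep(0, n_rho)
  if (ar) {
    mm <- tryCatch(ripm_params_from_moments(S0, mu0),
                   error = function(e) NULL)
    if (!is.null(mm) && mm$psi > 0 && all(mm$theta > 0)) {
      psi0 <- mm$psi
      theta0 <- mm$theta
      rho0 <- mm$rho
    }
  }
  g0 <- if (p) rep(0, p) else NULL
  par0 <- c(mu0, log(psi0), log(theta0), rho0, g0)

  obs <- !is.na(Y)
  pat <- apply(obs, 1, function(m) paste(as.integer(m), collapse = ""))
  pats <- unique(pat)
  pat_rows <- lapply(pats, function(pp) which(pat == pp))
  pat_mask <- lapply(pats, function(pp)
    as.logical(as.integer(strsplit(pp, "")[[1]])))

  unpack <- function(par) {
    list(mu = par[1:T], psi = exp(par[T + 1]),
         theta = exp(par[(T + 2):(2 * T + 1)]),
         rho = if (ar) par[(2 * T + 2):(2 * T + n_rho + 1)] else
           rep(0, T - 1),
         gamma = if (p) par[(2 * T + n_rho + 2):(2 * T + n_rho + p + 1)]
         else NULL)
  }

  negll <- function(par) {
    q <- unpack(par)
    S <- ripm_cov(q$psi, q$theta, q$rho)
    xb <- if (p) drop(X %*% q$gamma) else NULL
    nll <- 0
    for (i in seq_along(pats)) {
      m <- pat_mask[[i]]
      rows <- pat_rows[[i]]
      Sm <- S[m, m, drop = FALSE]
      ch <- tryCatch(chol(Sm), error = function(e) NULL)
      if (is.null(ch)) return(1e12)
      Yc <- Y[rows, m, drop = FALSE] -
        matrix(q$mu[m], length(rows), sum(m), byrow = TRUE)
      if (p) Yc <- Yc - xb[rows]
      z <- Yc %*% backsolve(ch, diag(sum(m)))
      nll <- nll + length(rows) * (sum(log(diag(ch))) +
                                     0.5 * sum(m) * log(2 * pi)) +
        0.5 * sum(z * z)
    }
    nll
  }

  ## fine ndeps: the default 1e-3 finite-difference step limits the
  ## attainable precision of the quasi-Newton search
  ctrl <- list(maxit = 2000, reltol = 1e-14,
               ndeps = rep(1e-6, length(par0)))
  o <- optim(par0, negll, method = "BFGS", control = ctrl)
  o <- optim(o$par, negll, method = "BFGS", hessian = TRUE,
             control = ctrl)

  ## central-difference gradient at the optimum, per-case scale
  gr <- vapply(seq_along(o$par), function(j) {
    h <- 1e-5 * max(1, abs(o$par[j]))
    e <- rep(0, length(o$par)); e[j] <- h
    (negll(o$par + e) - negll(o$par - e)) / (2 * h)
  }, numeric(1))
  grad_norm <- sqrt(sum(gr^2)) / n
  q <- unpack(o$par)
  params <- ripm_params(mu = q$mu, psi = q$psi, theta = q$theta,
                        rho = q$rho,
                        gamma = if (p) setNames(q$gamma, spec$predictors)
                        else NULL)
  vc <- tryCatch(solve(o$hessian), error = function(e)
    matrix(NA_real_, length(o$par), length(o$par)))

  standardized <- NULL
  se_gamma <- NULL
  predictor_moments <- NULL
  if (p) {
    Sx <- cov(X)
    predictor_moments <- list(mean = colMeans(X), cov = Sx)
    eta_sd <- sqrt(drop(t(q$gamma) %*% Sx %*% q$gamma) + q$psi)
    standardized <- setNames(q$gamma * sqrt(diag(Sx)) / eta_sd,
                             spec$predictors)
    gi <- (2 * T + n_rho + 2):(2 * T + n_rho + p + 1)
    se_gamma <- setNames(sqrt(pmax(diag(vc)[gi], 0)), spec$predictors)
  }

  structure(list(
    params = params, standardized = standardized, loglik = -o$value,
    n_used = n,
    convergence = list(converged = o$convergence == 0 &&
                         grad_norm < 1e-4,
                       grad_norm = grad_norm,
                       optim_status = o$convergence),
    vcov = vc, se_gamma = se_gamma, spec = spec,
    predictor_moments = predictor_moments,
    n_parameters = length(o$par)),
    class = "ripm_fit")
}

#' @export
print.ripm_fit <- function(x, ...) {
  cat("RI-PM fit (FIML): ", length(x$params$mu), " occasions, n = ",
      x$n_used, "\n", sep = "")
  cat("  loglik:", round(x$loglik, 2),
      " converged:", x$convergence$converged, "\n")
  print(x$params)
  if (!is.null(x$standardized)) {
    cat("  standardized paths:\n")
    print(round(x$standardized, 3))
  }
  invisible(x)
}

#' Tidy one-row-per-parameter summary of an RI-PM fit
#'
#' @param fit A [fit_ripm()] result.
#' @param ci Optional [cluster_bootstrap()] result whose statistics are
#'   named like `gamma_<predictor>`; its percentile intervals are joined
#'   onto the coefficient rows.
#' @return Tibble with columns `parameter, estimate, standardized,
#'   ci_lower, ci_upper`.
#' @export
ripm_tidy <- function(fit, ci = NULL) {
  stopifnot(inherits(fit, "ripm_fit"))
  p <- fit$params
  T <- length(p$mu)
  rows <- tibble::tibble(
    parameter = c(paste0("mu_", fit$spec$occasions), "psi",
                  paste0("theta_", fit$spec$occasions),
                  paste0("rho_", seq_len(T - 1)),
                  if (!is.null(p$gamma)) paste0("gamma_", names(p$gamma))),
    estimate = c(p$mu, p$psi, p$theta, p$rho, p$gamma),
    standardized = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
  if (!is.null(fit$standardized)) {
    idx <- match(paste0("gamma_", names(fit$standardized)),
                 rows$parameter)
    rows$standardized[idx] <- fit$standardized
  }
  if (!is.null(ci)) {
    idx <- match(rownames(ci$ci), rows$parameter)
    ok <- !is.na(idx)
    rows$ci_lower[idx[ok]] <- ci$ci[ok, "lower"]
    rows$ci_upper[idx[ok]] <- ci$ci[ok, "upper"]
  }
  rows
}

#' Cross-sectional multiple regression with standardized PGS coefficients
#'
#' Least-squares regression of one occasion of an outcome on a polygenic
#' score and control covariates, reporting standardized coefficients
#' (coefficient times predictor SD over outcome SD) for all predictors.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @return List of class `crosssection_fit`: `fit` (the `lm`),
#'   `standardized` (named vector), `n_used`.
#' @export
fit_crosssection <- function(data, outcome, predictors) {
  cols <- c(outcome, predictors)
  stopifnot(all(cols %in% names(data)))
  d <- data[complete.cases(data[, cols]), cols]
  if (nrow(d) < length(predictors) + 2)
    stop("need at least p + 2 complete cases")
  Xm <- as.matrix(d[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, Xm))
  if (qrX$rank < ncol(Xm) + 1) {
    bad <- predictors[qrX$pivot[seq(qrX$rank + 1,
                                    ncol(Xm) + 1)] - 1]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  f <- stats::as.formula(paste(outcome, "~",
                               paste(predictors, collapse = " + ")))
  fit <- lm(f, data = d)
  b <- coef(fit)[predictors]
  stdz <- b * apply(Xm, 2, sd) / sd(d[[outcome]])
  structure(list(fit = fit, standardized = stdz, n_used = nrow(d)),
            class = "crosssection_fit")
}

#' Likelihood-ratio test between nested fits
#'
#' `Delta chi^2 = 2 (loglik_full - loglik_reduced)` on degrees of freedom
#' equal to the parameter-count difference.  Both fits must use the same
#' cases; the reduced model must be nested in the full one.
#'
#' @param full,reduced Two [fit_ripm()] fits, or two [fit_path_model()]
#'   fits (for which the outcome equations are compared).
#' @return List with `delta_chi2`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced) UseMethod("lr_test")

#' @export
lr_test.ripm_fit <- function(full, reduced) {
  stopifnot(inherits(reduced, "ripm_fit"))
  if (full$n_used != reduced$n_used)
    stop("fits use different case sets (n = ", full$n_used, " vs ",
         reduced$n_used, ")")
  df <- full$n_parameters - reduced$n_parameters
  if (df < 0) stop("`full` must not have fewer parameters than `reduced`")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    stop("full model has lower likelihood: models are not nested ",
         "or did not converge")
  stat <- max(stat, 0)
  if (df == 0) {
    if (stat > 1e-6) stop("identical parameter counts but different ",
                          "likelihoods: models are not nested")
    return(list(delta_chi2 = 0, df = 0L, p_value = 1))
  }
  list(delta_chi2 = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
lr_test.path_fit <- function(full, reduced) {
  stopifnot(inherits(reduced, "path_fit"))
  if (full$n_used != reduced$n_used)
    stop("fits use different case sets")
  df <- length(full$outcome_coef) - length(reduced$outcome_coef)
  if (df <= 0) stop("`full` must have more outcome-equation parameters")
  n <- full$n_used
  stat <- n * log(reduced$outcome_rss / full$outcome_rss)
  stat <- max(stat, 0)
  list(delta_chi2 = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
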