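#' Random-intercept panel model parameter set
#'
#' Bundles the parameters of a univariate random-intercept panel model
#' (RI-PM): occasion intercepts, the stable-trait (random-intercept)
#' variance, occasion residual-factor variances, first-order autoregressive
#' coefficients linking successive residual factors, and (for conditional
#' models) regression coefficients of the random intercept on observed
#' predictors.
#'
#' The model for occasion `t` is `y_t = mu_t + eta + r_t`, with
#' `eta ~ N(Gamma'x, psi)` independent of the occasion process, and
#' `r_1 = e_1`, `r_t = rho_{t-1} r_{t-1} + e_t`, `e_t ~ N(0, theta_t)`.
#'
#' @param mu Numeric vector of occasion intercepts (length `T >= 2`).
#' @param psi Random-intercept variance (`> 0`).  In conditional models this
#'   is the residual variance of the intercept after regression on the
#'   predictors.
#' @param theta Numeric vector of occasion residual-factor variances
#'   (length `T`, all `> 0`).
#' @param rho Numeric vector of autoregressive coefficients between
#'   successive residual factors (length `T - 1`).  Use `rep(0, T - 1)` for
#'   a compound-symmetry model.
#' @param gamma Optional named numeric vector of regression coefficients of
#'   the random intercept on predictors (conditional model).
#' @return An object of class `ripm_params`.
#' @seealso [implied_moments()], [fit_ripm()]
#' @export
ripm_params <- function(mu, psi, theta, rho, gamma = NULL) {
  if (length(mu) < 2) stop("an RI-PM needs at least 2 occasions")
  if (length(theta) != length(mu))
    stop("`theta` must have one entry per occasion")
  if (length(rho) != length(mu) - 1)
    stop("`rho` must have one entry per adjacent occasion pair")
  if (!is.finite(psi) || psi <= 0) stop("`psi` must be > 0")
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all `theta` entries must be > 0")
  structure(
    list(mu = as.numeric(mu), psi = as.numeric(psi),
         theta = as.numeric(theta), rho = as.numeric(rho),
         gamma = gamma),
    class = "ripm_params")
}

#' @export
print.ripm_params <- function(x, ...) {
  cat("RI-PM parameters (", length(x$mu), " occasions)\n", sep = "")
  cat("  mu    :", paste(signif(x$mu, 4), collapse = " "), "\n")
  cat("  psi   :", signif(x$psi, 4), "\n")
  cat("  theta :", paste(signif(x$theta, 4), collapse = " "), "\n")
  cat("  rho   :", paste(signif(x$rho, 4), collapse = " "), "\n")
  if (!is.null(x$gamma))
    cat("  gamma :", paste(names(x$gamma), signif(x$gamma, 4),
                           collapse = ", "), "\n")
  invisible(x)
}

## variances of the occasion residual process r_t by the AR(1) recursion
ripm_resid_vars <- function(theta, rho) {
  T <- length(theta)
  v <- numeric(T)
  v[1] <- theta[1]
  if (T > 1) for (t in 2:T) v[t] <- rho[t - 1]^2 * v[t - 1] + theta[t]
  v
}

#' Model-implied occasion means and covariance of an RI-PM
#'
#' Assembles the mean vector and covariance matrix over occasions implied by
#' a set of RI-PM parameters.  The occasion residual process contributes
#' `Var(r_t) = rho_{t-1}^2 Var(r_{t-1}) + theta_t` with
#' `Cov(r_s, r_t) = prod(rho_s..rho_{t-1}) * Var(r_s)` for `s < t`; the
#' stable trait adds a constant `Var(eta)` to every cell.  For conditional
#' models (`gamma` present) the marginal trait variance is
#' `gamma' Sigma_x gamma + psi` and the mean vector is shifted by
#' `gamma' mean_x`.
#'
#' @param params An [ripm_params()] object.
#' @param predictor_moments Optional list with elements `mean` (predictor
#'   mean vector) and `cov` (predictor covariance matrix), required when
#'   `params$gamma` is present and marginal moments are wanted.
#' @return List with `mean` (length `T`) and `cov` (`T x T` matrix).
#' @export
#' @examples
#' p <- ripm_params(mu = c(0, 0, 0), psi = 1, theta = c(1, 1, 1),
#'                  rho = c(0.5, 0.5))
#' implied_moments(p)$cov
implied_moments <- function(params, predictor_moments = NULL) {
  stopifnot(inherits(params, "ripm_params"))
  T <- length(params$mu)
  v <- ripm_resid_vars(params$theta, params$rho)
  eta_var <- params$psi
  mu <- params$mu
  if (!is.null(params$gamma)) {
    if (!is.null(predictor_moments)) {
      g <- params$gamma
      Sx <- as.matrix(predictor_moments$cov)
      eta_var <- drop(t(g) %*% Sx %*% g) + params$psi
      mu <- mu + drop(crossprod(g, predictor_moments$mean))
    }
  }
  S <- matrix(eta_var, T, T)
  for (s in seq_len(T)) {
    S[s, s] <- S[s, s] + v[s]
    if (s < T) for (t in (s + 1):T) {
      cv <- prod(params$rho[s:(t - 1)]) * v[s]
      S[s, t] <- S[s, t] + cv
      S[t, s] <- S[s, t]
    }
  }
  list(mean = mu, cov = S)
}

## covariance of (eta, r_1..r_T) process only, given psi/theta/rho --
## used by the FIML likelihood and MAP scoring
ripm_cov <- function(psi, theta, rho) {
  T <- length(theta)
  v <- ripm_resid_vars(theta, rho)
  S <- matrix(psi, T, T)
  for (s in seq_len(T)) {
    S[s, s] <- S[s, s] + v[s]
    if (s < T) for (t in (s + 1):T) {
      cv <- prod(rho[s:(t - 1)]) * v[s]
      S[s, t] <- S[s, t] + cv
      S[t, s] <- S[s, t]
    }
  }
  S
}

#' Solve RI-PM parameters from a saturated covariance matrix
#'
#' The `T`-occasion RI-PM with autoregressive occasion residuals has
#' `2T` free (co)variance-structure parameters (`psi`, `theta_1..T`,
#' `rho_1..T-1`) against `T(T+1)/2` observed moments; for `T = 3` the model
#' is just-identified and this solve is exact.  Used for method-of-moments
#' starting values in [fit_ripm()] and to derive generator defaults from
#' published descriptive statistics.
#'
#' @param S Occasion covariance matrix (symmetric positive definite).
#' @param mu Optional occasion means carried through to the result.
#' @return An [ripm_params()] object.
#' @export
ripm_params_from_moments <- function(S, mu = rep(0, nrow(S))) {
  S <- as.matrix(S)
  T <- nrow(S)
  idx <- upper.tri(S, diag = TRUE)
  obj <- function(p) {
    psi <- exp(p[1]); theta <- exp(p[2:(T + 1)]); rho <- p[(T + 2):(2 * T)]
    M <- ripm_cov(psi, theta, rho)
    sum((M[idx] - S[idx])^2)
  }
  psi0 <- mean(S[upper.tri(S)])
  psi0 <- max(psi0, 1e-4)
  st <- c(log(psi0), log(pmax(diag(S) - psi0, 0.05 * diag(S))), rep(0, T - 1))
  o <- optim(st, obj, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  par <- o$par
  ## Gauss-Newton polish on the moment residuals to machine precision
  resid_fn <- function(p) {
    M <- ripm_cov(exp(p[1]), exp(p[2:(T + 1)]), p[(T + 2):(2 * T)])
    M[idx] - S[idx]
  }
  for (it in 1:20) {
    r0 <- resid_fn(par)
    if (max(abs(r0)) < 1e-12) break
    J <- vapply(seq_along(par), function(j) {
      h <- 1e-7 * max(1, abs(par[j]))
      e <- rep(0, length(par)); e[j] <- h
      (resid_fn(par + e) - resid_fn(par - e)) / (2 * h)
    }, numeric(length(r0)))
    step <- tryCatch(qr.solve(J, r0), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- par - step
    if (sum(resid_fn(cand)^2) < sum(r0^2)) par <- cand else break
  }
  ripm_params(mu = mu, psi = exp(par[1]), theta = exp(par[2:(T + 1)]),
              rho = par[(T + 2):(2 * T)])
}
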