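## shared fixtures and independent oracles used across test files

## data matrix whose *sample* correlation matrix equals R exactly:
## center, orthonormalize via QR, then impose chol(R)
make_exact_corr_data <- function(R, n, seed = 1) {
  set.seed(seed)
  k <- ncol(R)
  X <- matrix(rnorm(n * k), n, k)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  Q <- scale(Q, center = TRUE, scale = FALSE)   # re-center after QR
  Q <- qr.Q(qr(Q))
  Z <- Q %*% chol(R) * sqrt(n - 1)
  colnames(Z) <- colnames(R)
  as.data.frame(Z)
}

## direct simulation of the stable-trait + AR(1)-state process, written
## independently of the package internals (oracle for implied_moments)
simulate_ripm_process <- function(n, mu, psi, theta, rho, seed = 1) {
  set.seed(seed)
  T <- length(mu)
  eta <- rnorm(n, sd = sqrt(psi))
  r <- matrix(0, n, T)
  r[, 1] <- rnorm(n, sd = sqrt(theta[1]))
  for (t in 2:T) r[, t] <- rho[t - 1] * r[, t - 1] +
      rnorm(n, sd = sqrt(theta[t]))
  sweep(matrix(eta, n, T) + r, 2, mu, "+")
}

## simulate wide panel + 2 correlated predictors from known standardized
## stable-trait effects (total trait variance 1 on the latent scale)
simulate_conditional_panel <- function(n, g_std, r_x = -0.23,
                                       theta = c(0.9, 0.9, 0.9),
                                       rho = c(0.5, 0.5), seed = 1) {
  set.seed(seed)
  Sp <- matrix(c(1, r_x, r_x, 1), 2)
  X <- matrix(rnorm(n * 2), n, 2) %*% chol(Sp)
  psi_resid <- 1 - drop(t(g_std) %*% Sp %*% g_std)
  eta <- drop(X %*% g_std) + rnorm(n, sd = sqrt(psi_resid))
  T <- length(theta)
  r <- matrix(0, n, T)
  r[, 1] <- rnorm(n, sd = sqrt(theta[1]))
  for (t in 2:T) r[, t] <- rho[t - 1] * r[, t - 1] +
      rnorm(n, sd = sqrt(theta[t]))
  d <- as.data.frame(matrix(eta, n, T) + r)
  names(d) <- paste0("y", seq_len(T))
  d$x1 <- X[, 1]
  d$x2 <- X[, 2]
  d
}

## brute-force posterior mean of eta given observed occasions, by
## quadrature on a fine grid (oracle for map_scores)
quadrature_posterior_mean <- function(y_obs, mu_obs, V_obs, psi,
                                      grid = seq(-8, 8, length.out = 4001)) {
  Vi <- solve(V_obs)
  logpost <- vapply(grid, function(e) {
    d <- y_obs - mu_obs - e
    -0.5 * e^2 / psi - 0.5 * drop(t(d) %*% Vi %*% d)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  sum(grid * w) / sum(w)
}

## covariance of the AR(1) occasion-residual vector alone (no stable trait)
ar_resid_cov <- function(theta, rho) {
  T <- length(theta)
  v <- numeric(T)
  v[1] <- theta[1]
  for (t in 2:T) v[t] <- rho[t - 1]^2 * v[t - 1] + theta[t]
  V <- diag(v)
  for (s in 1:(T - 1)) for (t in (s + 1):T) {
    V[s, t] <- V[t, s] <- prod(rho[s:(t - 1)]) * v[s]
  }
  V
}

## minimal ripm_fit-shaped object for scoring tests with known parameters
fake_ripm_fit <- function(mu, psi, theta, rho, occasions,
                          predictors = character(), gamma = NULL) {
  structure(list(
    params = ripm_params(mu, psi, theta, rho, gamma = gamma),
    spec = ripm_spec(occasions, predictors),
    convergence = list(converged = TRUE)),
    class = "ripm_fit")
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(n_families = 400),
                                seed = 20260101)
    cache
  }
})
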