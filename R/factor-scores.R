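#' Maximum a posteriori random-intercept factor scores
#'
#' Computes each person's posterior mean of the stable trait `eta` given
#' their observed occasions under a fitted RI-PM — which equals the
#' posterior mode under normality, hence the MAP score.  With observed
#' occasions `y_obs` and model-implied covariance `Sigma_obs`,
#' `score = Gamma'x + psi * 1' Sigma_obs^{-1} (y_obs - mu_obs - 1 Gamma'x)`
#' (the `Gamma'x` terms drop for unconditional fits).  Persons with no
#' observed occasion get a missing score.
#'
#' For downstream regressions of the scores on predictors, use scores from
#' an unconditional fit: conditional-fit scores already contain the
#' predictor-driven mean component.
#'
#' @param fit A converged [fit_ripm()] result.
#' @param data Wide data frame with the fit's occasion (and, for
#'   conditional fits, predictor) columns.
#' @param id Optional name of an identifier column to carry through
#'   (default: `person_id` when present, otherwise the row number).
#' @return Tibble of class `factor_scores`: `person_id`, `score`,
#'   `n_occasions_used`.
#' @export
map_scores <- function(fit, data, id = NULL) {
  stopifnot(inherits(fit, "ripm_fit"))
  if (!fit$convergence$converged)
    warning("scoring from a fit flagged as non-converged")
  spec <- fit$spec
  Y <- as.matrix(data[, spec$occasions, drop = FALSE])
  n <- nrow(Y)
  p <- length(spec$predictors)
  xb <- if (p) {
    X <- as.matrix(data[, spec$predictors, drop = FALSE])
    drop(X %*% fit$params$gamma)
  } else rep(0, n)
  pr <- fit$params
  S <- ripm_cov(pr$psi, pr$theta, pr$rho)
  T <- ncol(Y)

  obs <- !is.na(Y)
  pat <- apply(obs, 1, function(m) paste(as.integer(m), collapse = ""))
  scores <- rep(NA_real_, n)
  used <- rowSums(obs)
  for (pp in unique(pat)) {
    m <- as.logical(as.integer(strsplit(pp, "")[[1]]))
    rows <- which(pat == pp)
    if (!any(m)) next
    w <- pr$psi * solve(S[m, m, drop = FALSE], rep(1, sum(m)))
    Yc <- Y[rows, m, drop = FALSE] -
      matrix(pr$mu[m], length(rows), sum(m), byrow = TRUE) - xb[rows]
    scores[rows] <- xb[rows] + drop(Yc %*% w)
  }
  if (is.null(id)) id <- if ("person_id" %in% names(data)) "person_id"
  ids <- if (!is.null(id)) data[[id]] else seq_len(n)
  out <- tibble::tibble(person_id = ids, score = scores,
                        n_occasions_used = as.integer(used))
  attr(out, "provenance") <- list(
    occasions = spec$occasions, predictors = spec$predictors,
    loglik = fit$loglik)
  class(out) <- c("factor_scores", class(out))
  out
}

#' Reliability of a MAP score for an observation pattern
#'
#' The ratio `Var(score) / psi = psi * 1' Sigma_obs^{-1} 1` of the score
#' variance to the stable-trait variance, in `[0, 1]`; a diagnostic for the
#' two-step design in which scores from one model feed a second model.
#'
#' @param fit A [fit_ripm()] result.
#' @param pattern Logical vector, one entry per occasion, `TRUE` where
#'   observed; at least one `TRUE`.
#' @return Reliability fraction in `[0, 1]`.
#' @export
#' @examples
#' # a single occasion with psi = theta gives shrinkage 0.5
score_reliability <- function(fit, pattern) {
  stopifnot(inherits(fit, "ripm_fit"))
  pr <- fit$params
  pattern <- as.logical(pattern)
  if (length(pattern) != length(pr$mu))
    stop("pattern length must match the number of occasions")
  if (!any(pattern)) stop("empty observation pattern")
  S <- ripm_cov(pr$psi, pr$theta, pr$rho)
  m <- pattern
  drop(pr$psi * sum(solve(S[m, m, drop = FALSE], rep(1, sum(m)))))
}
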