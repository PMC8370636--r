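#' One-factor confirmatory factor analysis of discipline items
#'
#' Fits a single-factor linear CFA by maximum likelihood to the six
#' combined discipline items (treated as continuous), with the factor
#' variance fixed to 1, and returns regression-method factor scores with
#' sample mean 0.  Items are analysed on the correlation scale, so the
#' reported loadings are standardized.  Persons with partially observed
#' item vectors are scored from their observed items only (the regression
#' weights are recomputed per missingness pattern).
#'
#' With exactly two indicators the one-factor model is not identified
#' without a constraint; the loadings are then constrained equal
#' (tau-equivalent), for which the closed-form solution is
#' `lambda = sqrt(r12)`.
#'
#' @param items Numeric matrix or data frame, one row per person, one
#'   column per item; `NA`s allowed.
#' @param min_n Minimum number of rows with at least `ncol/2` observed
#'   items (default 50; relaxed automatically for toy inputs with < 50
#'   rows only via this argument).
#' @return List of class `discipline_cfa`:
#'   `loadings` (standardized), `uniquenesses`, `scores` (regression-method
#'   factor scores, mean 0), `converged`, `heywood` (any uniqueness at its
#'   lower bound), `degenerate` (fewer than two salient loadings, i.e. no
#'   common factor), `iterations`,
#'   `objective` (ML discrepancy).
#' @export
fit_discipline_cfa <- function(items, min_n = 50) {
  X <- as.matrix(items)
  storage.mode(X) <- "double"
  p <- ncol(X)
  usable <- rowSums(!is.na(X)) >= max(2, ceiling(p / 2))
  if (sum(usable) < min_n)
    stop("need at least ", min_n, " sufficiently complete item vectors, ",
         "got ", sum(usable))
  cc <- complete.cases(X)
  R <- cor(X[cc, , drop = FALSE])
  sds <- apply(X[cc, , drop = FALSE], 2, sd)
  if (any(sds == 0)) stop("constant item column(s): ",
                          paste(which(sds == 0), collapse = ", "))

  eq_constraint <- p == 2
  lb <- 0.005   # uniqueness lower bound; hitting it flags a Heywood case
  fml <- function(lam, psi) {
    S <- tcrossprod(lam) + diag(psi, nrow = p)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    ld + sum(diag(chol2inv(ch) %*% R)) - determinant(R)$modulus[1] - p
  }
  if (eq_constraint) {
    obj <- function(par) {
      lam <- rep(tanh(par[1]), 2)
      fml(lam, pmax(1 - lam^2, lb))
    }
    o <- optim(atanh(min(0.9, sqrt(max(R[1, 2], 0.01)))), obj,
               method = "BFGS", control = list(maxit = 500))
    lam <- rep(tanh(o$par[1]), 2)
    psi <- pmax(1 - lam^2, lb)
  } else {
    st <- sqrt(pmax(colMeans(abs(R)) - 1 / p, 0.05))
    obj <- function(par) {
      lam <- par[1:p]
      psi <- lb + exp(par[(p + 1):(2 * p)])
      fml(lam, psi)
    }
    o <- optim(c(st, log(pmax(1 - st^2 - lb, 0.05))), obj,
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
    lam <- o$par[1:p]
    psi <- lb + exp(o$par[(p + 1):(2 * p)])
  }
  if (mean(lam) < 0) lam <- -lam   # sign convention: positive mean loading
  heywood <- any(psi <= lb + 1e-6)
  ## a factor needs at least two salient indicators; on uncorrelated items
  ## the ML solution degenerates to a single-variable "factor"
  degenerate <- sum(abs(lam) >= 0.3) < 2 || mean(abs(lam)) < 0.1

  ## regression-method scores per missingness pattern, on standardized items
  Z <- sweep(sweep(X, 2, colMeans(X, na.rm = TRUE)), 2, sds, "/")
  scores <- rep(NA_real_, nrow(X))
  pat <- apply(!is.na(Z), 1, function(m) paste(as.integer(m), collapse = ""))
  for (pt in unique(pat[usable])) {
    m <- as.logical(as.integer(strsplit(pt, "")[[1]]))
    if (!any(m)) next
    Sm <- tcrossprod(lam[m]) + diag(psi[m], nrow = sum(m))
    w <- solve(Sm, lam[m])
    idx <- which(pat == pt & usable)
    scores[idx] <- Z[idx, m, drop = FALSE] %*% w
  }
  scores <- scores - mean(scores, na.rm = TRUE)

  structure(list(loadings = lam, uniquenesses = psi, scores = scores,
                 converged = o$convergence == 0, heywood = heywood,
                 degenerate = degenerate, iterations = o$counts,
                 objective = o$value),
            class = "discipline_cfa")
}

#' @export
print.discipline_cfa <- function(x, ...) {
  cat("1-factor ML CFA:", length(x$loadings), "items\n")
  cat("  loadings :", paste(round(x$loadings, 3), collapse = " "), "\n")
  cat("  converged:", x$converged,
      if (x$heywood) " [Heywood case]" else "",
      if (x$degenerate) " [degenerate: loadings ~ 0]" else "", "\n")
  invisible(x)
}
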