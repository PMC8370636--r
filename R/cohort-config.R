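## ---- internal calibration helpers -------------------------------------

## per-occasion probabilities of clamp(round(m + k*Z), 0, max_cat), Z~N(0,1)
binned_probs <- function(m, k, max_cat = 6L) {
  j <- 0:max_cat
  lo <- (j - 0.5 - m) / k
  hi <- (j + 0.5 - m) / k
  p <- pnorm(hi) - pnorm(lo)
  p[1] <- pnorm(hi[1])
  p[max_cat + 1] <- 1 - pnorm(lo[max_cat + 1])
  p
}

## solve (m, k) so the clamp-round transform of a standard normal hits a
## target mean and SD on the 0..max_cat scale
solve_binned_moments <- function(target_mean, target_sd, max_cat = 6L) {
  j <- 0:max_cat
  obj <- function(par) {
    p <- binned_probs(par[1], exp(par[2]), max_cat)
    mm <- sum(j * p)
    ss <- sqrt(sum(j^2 * p) - mm^2)
    (mm - target_mean)^2 + (ss - target_sd)^2
  }
  o <- optim(c(target_mean, log(target_sd)), obj,
             control = list(maxit = 10000, reltol = 1e-15))
  if (o$value > 1e-8)
    stop("binned-moment solve failed for mean = ", target_mean,
         ", sd = ", target_sd)
  c(m = o$par[1], k = exp(o$par[2]))
}

## correlation between a standard normal latent and its categorisation at
## fixed standardized thresholds z (categories 1..K)
categorical_attenuation <- function(z) {
  K <- length(z) + 1
  p <- diff(c(0, pnorm(z), 1))
  cats <- seq_len(K)
  m <- sum(cats * p)
  s <- sqrt(sum(cats^2 * p) - m^2)
  ph <- c(0, dnorm(z), 0)
  sum(cats * (ph[1:K] - ph[2:(K + 1)])) / s
}

## informant-noise SD giving inter-informant correlation r for reports
## y + d and y - d around a composite with variance v
informant_tau <- function(v, r) sqrt(v * (1 - r) / (1 + r))

trait_names <- function() {
  c("gpa", "motiv_sp", "motiv_teacher", "discipline", "cigs_per_day")
}

## ---- configuration ------------------------------------------------------

#' Configuration of the synthetic twin-family cohort generator
#'
#' Builds the full parameterization used by [simulate_cohort()].  The
#' default values reproduce, in population, the published descriptive
#' statistics returned by [reference_targets()]: trait means/SDs and lag-1
#' stabilities at each occasion, the -0.23 correlation between the smoking
#' and education polygenic scores, standardized polygenic-score effects on
#' each trait's stable component, the correlation structure among the five
#' stable traits, the six educational-attainment category shares, and the
#' 0.27 age-attainment correlation.  Stable-trait/autoregressive
#' parameters per trait are solved exactly from the published occasion SDs
#' and autocorrelations via [ripm_params_from_moments()].
#'
#' @param n_families Number of twin families to simulate.
#' @param prop_mz Proportion of monozygotic pairs (default 1205/1881).
#' @param prop_younger_cohort Proportion of families in the younger cohort
#'   (first assessed at age 11; the rest enter at age 17).
#' @param pgs_cross_corr Correlation between the smoking and education
#'   polygenic scores within person.
#' @param dz_pgs_within_pair_corr Within-pair polygenic-score correlation
#'   for dizygotic twins (expected sib sharing, 0.5).
#' @param familial_a,familial_c Additive-genetic and shared-environment
#'   fractions of the non-polygenic-score stable-trait variance, governing
#'   MZ/DZ twin similarity (MZ share the additive component fully, DZ share
#'   half; the shared-environment component is common to both twins).
#' @param p_female Probability that a (same-sex) pair is female.
#' @param teacher_k_probs Probabilities of a participant having 1, 2 or 3
#'   teacher informants.
#' @param teacher_within_r Assumed correlation among reports from different
#'   teachers of the same child (not published; see the package vignette).
#' @param missingness Named list of rates: `retention` (named by age,
#'   pair-level visit retention), `teacher` (named by age, person-level
#'   teacher-report availability), `ea_missing` (probability attainment is
#'   unobserved).
#' @param cig_bins Breakpoints mapping raw cigarettes/day to the 0-6 scale;
#'   see [code_cigarettes()].
#' @param latent_r2_attainment Proportion of latent attainment-liability
#'   variance explained by all predictors including age.  The default is
#'   chosen so the observed-scale R^2 is about 0.36 after categorisation.
#' @param seed Integer seed used by [simulate_cohort()] when none is given.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_families = 50)
#' cfg$traits$gpa$mu
cohort_config <- function(n_families = 1881L,
                          prop_mz = 1205 / 1881,
                          prop_younger_cohort = 1255 / 1881,
                          pgs_cross_corr = -0.23,
                          dz_pgs_within_pair_corr = 0.5,
                          familial_a = 0.4,
                          familial_c = 0.3,
                          p_female = 0.52,
                          teacher_k_probs = c(0.25, 0.45, 0.30),
                          teacher_within_r = 0.70,
                          missingness = list(
                            retention = c("14" = 0.914, "17" = 0.863,
                                          "21" = 0.717, "24" = 0.866),
                            teacher = c("11" = 0.699, "14" = 0.720,
                                        "17" = 0.598),
                            ea_missing = 0.079),
                          cig_bins = NULL,
                          latent_r2_attainment = NULL,
                          seed = 1881L) {
  call_args <- list(
    n_families = as.integer(n_families), prop_mz = prop_mz,
    prop_younger_cohort = prop_younger_cohort,
    pgs_cross_corr = pgs_cross_corr,
    dz_pgs_within_pair_corr = dz_pgs_within_pair_corr,
    familial_a = familial_a, familial_c = familial_c, p_female = p_female,
    teacher_k_probs = teacher_k_probs, teacher_within_r = teacher_within_r,
    missingness = missingness, cig_bins = cig_bins,
    latent_r2_attainment = latent_r2_attainment, seed = as.integer(seed))

  tg <- reference_targets()
  desc <- tg$descriptives
  traits <- list()

  ## academic traits: exact moment solve from published SDs/stabilities
  for (tr in c("gpa", "motiv_sp", "motiv_teacher", "discipline")) {
    d <- desc[desc$trait == tr, ]
    sds <- d$sd
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- d$r_lag1[2]
    R[2, 3] <- R[3, 2] <- d$r_lag1[3]
    R[1, 3] <- R[3, 1] <- d$r_lag2[3]
    S <- diag(sds) %*% R %*% diag(sds)
    pr <- ripm_params_from_moments(S, mu = d$mean)
    r_inf <- tg$informant_r$r[match(tr, tg$informant_r$trait)]
    tot <- pr$psi + ripm_resid_vars(pr$theta, pr$rho)
    traits[[tr]] <- list(
      occasions = d$occasion, mu = pr$mu, psi = pr$psi,
      theta = pr$theta, rho = pr$rho,
      informant_r = r_inf,
      informant_tau = if (tr != "discipline")
        informant_tau(tot, r_inf) else NULL)
  }

  ## cigarettes per day: latent stable+AR process, standardized per
  ## occasion and pushed through a calibrated clamp-round transform
  dcig <- desc[desc$trait == "cigs_per_day", ]
  cig <- list(occasions = dcig$occasion, psi = 1,
              theta = c(0.90, 0.718, 0.718, 0.718),
              rho = c(0.45, 0.45, 0.45))
  cig$mu <- rep(0, 4)
  cig$latent_sd <- sqrt(cig$psi + ripm_resid_vars(cig$theta, cig$rho))
  bins <- t(vapply(seq_len(nrow(dcig)),
                   function(i) solve_binned_moments(dcig$mean[i], dcig$sd[i]),
                   numeric(2)))
  cig$bin_m <- bins[, 1]
  cig$bin_k <- bins[, 2]
  ## representative raw cigarettes/day per 0-6 category, the inverse of the
  ## default code_cigarettes() binning
  cig$raw_per_category <- c(0, 0.5, 3, 8, 13, 17.5, 25)
  traits$cigs_per_day <- cig

  ## standardized PGS -> stable-trait effects and residual correlations
  trn <- trait_names()
  pt <- tg$path_truths
  G <- cbind(
    pgs_smoking = pt$beta[match(paste0("ri_", trn),
                                ifelse(pt$pgs == "pgs_smoking", pt$target, ""))],
    pgs_edu = pt$beta[match(paste0("ri_", trn),
                            ifelse(pt$pgs == "pgs_edu", pt$target, ""))])
  rownames(G) <- trn
  Sp <- matrix(c(1, pgs_cross_corr, pgs_cross_corr, 1), 2)
  R_eta <- tg$mediation_corr[paste0("ri_", trn), paste0("ri_", trn)]
  D <- R_eta - G %*% Sp %*% t(G)   # residual covariance of standardized RIs
  dimnames(D) <- list(trn, trn)

  ## attainment liability model
  shares <- tg$ea_shares$share
  cum <- cumsum(shares)[1:5] / 100
  z_thr <- qnorm(cum)
  lambda <- categorical_attenuation(z_thr)
  if (is.null(latent_r2_attainment)) latent_r2_attainment <- 0.36 / lambda^2
  b_ri <- pt$beta[pt$pgs == "outcome"]
  names(b_ri) <- trn
  b_pgs <- c(pgs_smoking = pt$beta[pt$target == "attainment_direct" &
                                     pt$pgs == "pgs_smoking"],
             pgs_edu = pt$beta[pt$target == "attainment_direct" &
                                 pt$pgs == "pgs_edu"])
  Sig7 <- rbind(cbind(R_eta, G %*% Sp), cbind(t(G %*% Sp), Sp))
  w_all <- c(b_ri, b_pgs)
  v_nonage <- drop(t(w_all) %*% Sig7 %*% w_all)
  c_age <- tg$ea_age_r / lambda       # needed latent age correlation
  var_L <- v_nonage / (latent_r2_attainment - c_age^2)
  if (var_L <= 0)
    stop("attainment calibration infeasible: latent R^2 must exceed ",
         "the squared latent age correlation")
  b_age <- c_age * sqrt(var_L)
  resid_var <- var_L * (1 - latent_r2_attainment)

  ea_model <- list(
    b_ri = b_ri, b_pgs = b_pgs, b_age = b_age,
    resid_var = resid_var, sd_latent = sqrt(var_L),
    thresholds = z_thr, lambda = lambda,
    age_mean = 29.4, age_sd = 3.9)

  cfg <- structure(
    list(n_families = as.integer(n_families), prop_mz = prop_mz,
         prop_younger_cohort = prop_younger_cohort,
         pgs_cross_corr = pgs_cross_corr,
         dz_pgs_within_pair_corr = dz_pgs_within_pair_corr,
         familial = c(a = familial_a, c = familial_c),
         p_female = p_female,
         teacher_k_probs = teacher_k_probs / sum(teacher_k_probs),
         teacher_within_r = teacher_within_r,
         traits = traits, ri_effects = G, ri_resid_cov = D,
         ea_model = ea_model, missingness = missingness,
         cig_bins = cig_bins, seed = as.integer(seed),
         call_args = call_args),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a [cohort_config()]: positive
#' variance parameters, a symmetric positive-definite residual correlation
#' structure among the stable traits, strictly increasing attainment
#' thresholds, and rates/fractions inside `[0, 1]`.  Called by
#' [cohort_config()] and by [simulate_cohort()]; errors name the offending
#' block.
#'
#' @param config A `cohort_config` object.
#' @return The config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) stop("not a cohort_config object")
  fr <- c(prop_mz = config$prop_mz,
          prop_younger_cohort = config$prop_younger_cohort,
          p_female = config$p_female,
          familial_a = config$familial["a"], familial_c = config$familial["c"],
          unlist(config$missingness))
  bad <- fr[!is.finite(fr) | fr < 0 | fr > 1]
  if (length(bad))
    stop("fractions/rates outside [0, 1]: ",
         paste(names(bad), collapse = ", "))
  if (sum(config$familial) > 1)
    stop("familial fractions a + c exceed 1")
  for (tr in names(config$traits)) {
    p <- config$traits[[tr]]
    if (p$psi <= 0 || any(p$theta <= 0))
      stop("non-positive variance parameter in trait block '", tr, "'")
  }
  D <- config$ri_resid_cov
  if (any(abs(D - t(D)) > 1e-10))
    stop("ri_resid_cov block is not symmetric")
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("ri_resid_cov block is not positive definite ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  thr <- config$ea_model$thresholds
  if (any(diff(thr) <= 0))
    stop("ea_model thresholds are not strictly increasing")
  if (abs(config$pgs_cross_corr) >= 1 ||
      config$dz_pgs_within_pair_corr < 0 ||
      config$dz_pgs_within_pair_corr > 1)
    stop("pgs correlation parameters out of range")
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  families          :", x$n_families,
      sprintf("(%.1f%% MZ, %.1f%% younger cohort)", 100 * x$prop_mz,
              100 * x$prop_younger_cohort), "\n")
  cat("  traits            :", paste(names(x$traits), collapse = ", "), "\n")
  cat("  pgs cross-corr    :", x$pgs_cross_corr, "\n")
  cat("  familial fractions: A =", x$familial["a"], ", C =",
      x$familial["c"], "\n")
  cat("  seed              :", x$seed, "\n")
  invisible(x)
}

#' Read/write a cohort configuration as YAML
#'
#' Only the user-settable arguments of [cohort_config()] are serialized;
#' the derived calibration (moment solves, thresholds) is recomputed
#' deterministically on read, so a round trip reproduces the configuration
#' exactly.
#'
#' @param config A `cohort_config` object.
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  args <- config$call_args
  args$missingness$retention <- as.list(args$missingness$retention)
  args$missingness$teacher <- as.list(args$missingness$teacher)
  yaml::write_yaml(args, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  args <- yaml::read_yaml(path)
  args$missingness$retention <- unlist(args$missingness$retention)
  args$missingness$teacher <- unlist(args$missingness$teacher)
  do.call(cohort_config, args)
}
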