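#' Simulate a twin-family cohort
#'
#' Generates a fully observed synthetic cohort with the structure the
#' downstream models assume: same-sex MZ/DZ twin pairs in a younger
#' (assessed from age 11) and an older (from age 17) cohort; two
#' standardized polygenic scores correlated within person, fully shared by
#' MZ co-twins and correlated 0.5 within DZ pairs; five traits whose values
#' follow a stable-trait plus AR(1)-state process
#' `y_t = mu_t + eta + r_t`, `r_t = rho_{t-1} r_{t-1} + e_t`; standardized
#' stable components regressed on the polygenic scores with residual
#' correlations and an ACE-style familial decomposition; multi-informant
#' reports (twin/mother for GPA and motivation, 1-3 teachers for
#' teacher-rated motivation); integer 0-6 cigarettes-per-day values from a
#' calibrated categorisation of the latent smoking process, emitted as raw
#' cigarettes/day counts; and a 6-category educational-attainment outcome
#' from a thresholded latent liability with an age effect.
#'
#' Informant reports for two-informant traits are generated as `y + d` and
#' `y - d`, so their mean reproduces the trait value exactly while the
#' inter-informant correlation matches the configured target; teacher
#' report noise is centered within person for the same reason.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.  The same seed
#'   yields a byte-identical dataset.
#' @param keep_latent Also return the simulated standardized stable traits
#'   (one column per trait) in a `latent` element — useful for validating
#'   factor-score recovery against the generating truth.
#' @return An object of class `panel_data`: a list with
#'   \describe{
#'     \item{persons}{one row per person: ids, zygosity, sex, cohort,
#'       ancestry principal components `pc1..pc5` (pure noise covariates),
#'       and the two polygenic scores.}
#'     \item{panel}{long table of (person_id, trait, occasion, informant,
#'       value, observed).}
#'     \item{attainment}{one row per person: `ea_category` (1-6) and
#'       `age_at_report`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @seealso [apply_missingness()], [build_composites()], [export_panel()]
#' @export
#' @examples
#' cfg <- cohort_config(n_families = 20)
#' dat <- simulate_cohort(cfg)
#' dplyr::count(dat$panel, trait, informant)
simulate_cohort <- function(config, seed = config$seed,
                            keep_latent = FALSE) {
  validate_cohort_config(config)
  set.seed(seed)
  F <- config$n_families
  if (F == 0) return(empty_panel_data(config))
  n <- 2L * F

  ## family design
  zyg_f <- ifelse(runif(F) < config$prop_mz, "MZ", "DZ")
  cohort_f <- ifelse(runif(F) < config$prop_younger_cohort,
                     "younger", "older")
  sex_f <- ifelse(runif(F) < config$p_female, "F", "M")
  fam <- rep(seq_len(F), each = 2)
  twin_no <- rep(1:2, F)
  zyg <- zyg_f[fam]; cohort <- cohort_f[fam]; sex <- sex_f[fam]

  ## polygenic scores: bivariate within person, shared across co-twins
  Lp <- chol(matrix(c(1, config$pgs_cross_corr,
                      config$pgs_cross_corr, 1), 2))
  rdz <- config$dz_pgs_within_pair_corr
  g_f <- matrix(rnorm(F * 2), F, 2) %*% Lp       # pair-shared component
  g_i <- matrix(rnorm(n * 2), n, 2) %*% Lp       # individual component
  mz <- zyg == "MZ"
  pgs <- matrix(NA_real_, n, 2)
  pgs[mz, ] <- g_f[fam[mz], ]
  pgs[!mz, ] <- sqrt(rdz) * g_f[fam[!mz], ] + sqrt(1 - rdz) * g_i[!mz, ]
  colnames(pgs) <- c("pgs_smoking", "pgs_edu")

  ## standardized stable traits: PGS effects + ACE-structured residual
  G <- config$ri_effects
  D <- config$ri_resid_cov
  fa <- config$familial["a"]; fc <- config$familial["c"]
  fe <- 1 - fa - fc
  a_f <- matrix(rnorm(F * 5), F, 5)
  a_i <- matrix(rnorm(n * 5), n, 5)
  a_tw <- matrix(NA_real_, n, 5)
  a_tw[mz, ] <- a_f[fam[mz], ]
  a_tw[!mz, ] <- sqrt(0.5) * a_f[fam[!mz], ] + sqrt(0.5) * a_i[!mz, ]
  c_tw <- matrix(rnorm(F * 5), F, 5)[fam, ]
  e_tw <- matrix(rnorm(n * 5), n, 5)
  x_std <- sqrt(fa) * a_tw + sqrt(fc) * c_tw + sqrt(fe) * e_tw
  delta <- x_std %*% chol(D)
  eta_std <- pgs %*% t(G) + delta
  colnames(eta_std) <- rownames(G)

  persons <- tibble::tibble(
    family_id = fam, person_id = sprintf("p%05d_%d", fam, twin_no),
    zygosity = zyg, sex = sex, cohort = cohort)
  pcs <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  persons <- dplyr::bind_cols(persons, tibble::as_tibble(pcs),
                              tibble::as_tibble(pgs))

  blocks <- vector("list", 0)
  add_block <- function(pid, trait, occ, informant, value) {
    tibble::tibble(person_id = pid, trait = trait, occasion = occ,
                   informant = informant, value = value, observed = TRUE)
  }

  for (tr in c("gpa", "motiv_sp", "motiv_teacher", "discipline")) {
    p <- config$traits[[tr]]
    Tocc <- length(p$occasions)
    r <- ar_process(n, p$theta, p$rho)
    y <- sweep(sqrt(p$psi) * eta_std[, tr] + r, 2, p$mu, "+")
    pid3 <- rep(persons$person_id, Tocc)
    occ3 <- rep(p$occasions, each = n)
    blocks[[length(blocks) + 1]] <-
      add_block(pid3, tr, occ3, "composite", as.vector(y))
    if (tr %in% c("gpa", "motiv_sp")) {
      d <- sapply(seq_len(Tocc),
                  function(t) rnorm(n, sd = p$informant_tau[t]))
      ## "twin" covers both the twin's own GPA report and the
      ## motivation self-report
      blocks[[length(blocks) + 1]] <-
        add_block(pid3, tr, occ3, "twin", as.vector(y + d))
      blocks[[length(blocks) + 1]] <-
        add_block(pid3, tr, occ3, "mother", as.vector(y - d))
    }
    if (tr == "motiv_teacher") {
      k <- sample.int(3, n, replace = TRUE, prob = config$teacher_k_probs)
      idx <- rep(seq_len(n), k)
      tno <- sequence(k)
      tot <- p$psi + ripm_resid_vars(p$theta, p$rho)
      tau_t <- sqrt(tot * (1 - config$teacher_within_r) /
                      config$teacher_within_r)
      for (t in seq_len(Tocc)) {
        d <- rnorm(length(idx), sd = tau_t[t])
        d <- d - stats::ave(d, idx)
        blocks[[length(blocks) + 1]] <-
          add_block(persons$person_id[idx], tr, p$occasions[t],
                    paste0("teacher_", tno), y[idx, t] + d)
      }
    }
  }

  ## cigarettes per day: latent process -> calibrated 0-6 categories ->
  ## representative raw counts
  p <- config$traits$cigs_per_day
  r <- ar_process(n, p$theta, p$rho)
  z <- sqrt(p$psi) * eta_std[, "cigs_per_day"] + r
  zs <- sweep(z, 2, p$latent_sd, "/")
  cats <- pmin(pmax(round(sweep(sweep(zs, 2, p$bin_k, "*"),
                                2, p$bin_m, "+")), 0), 6)
  raw <- matrix(p$raw_per_category[cats + 1], n, length(p$occasions))
  blocks[[length(blocks) + 1]] <-
    add_block(rep(persons$person_id, length(p$occasions)), "cigs_per_day",
              rep(p$occasions, each = n), "twin", as.vector(raw))

  panel <- dplyr::bind_rows(blocks)
  panel <- dplyr::arrange(panel, person_id, trait, occasion, informant)

  ## educational attainment from thresholded latent liability
  em <- config$ea_model
  age <- rnorm(n, em$age_mean, em$age_sd)
  L <- drop(eta_std %*% em$b_ri) + drop(pgs %*% em$b_pgs) +
    em$b_age * (age - em$age_mean) / em$age_sd +
    rnorm(n, sd = sqrt(em$resid_var))
  ea <- findInterval(L / em$sd_latent, em$thresholds) + 1L
  attainment <- tibble::tibble(
    person_id = persons$person_id, ea_category = ea,
    age_at_report = age, observed = TRUE)
  persons$age_at_last_assessment <- age

  out <- list(persons = persons, panel = panel,
              attainment = attainment, config = config)
  if (keep_latent) {
    lat <- tibble::as_tibble(eta_std)
    names(lat) <- paste0("eta_", colnames(eta_std))
    out$latent <- dplyr::bind_cols(
      tibble::tibble(person_id = persons$person_id), lat)
  }
  structure(out, class = "panel_data")
}

## first-order autoregressive occasion process, n persons x T occasions
ar_process <- function(n, theta, rho) {
  T <- length(theta)
  r <- matrix(NA_real_, n, T)
  r[, 1] <- rnorm(n, sd = sqrt(theta[1]))
  if (T > 1) for (t in 2:T)
    r[, t] <- rho[t - 1] * r[, t - 1] + rnorm(n, sd = sqrt(theta[t]))
  r
}

empty_panel_data <- function(config) {
  structure(list(
    persons = tibble::tibble(
      family_id = integer(), person_id = character(),
      zygosity = character(), sex = character(), cohort = character(),
      pc1 = double(), pc2 = double(), pc3 = double(), pc4 = double(),
      pc5 = double(), pgs_smoking = double(), pgs_edu = double(),
      age_at_last_assessment = double()),
    panel = tibble::tibble(
      person_id = character(), trait = character(), occasion = integer(),
      informant = character(), value = double(), observed = logical()),
    attainment = tibble::tibble(
      person_id = character(), ea_category = integer(),
      age_at_report = double(), observed = logical()),
    config = config), class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("<panel_data> ", nrow(x$persons), " persons in ",
      length(unique(x$persons$family_id)), " families\n", sep = "")
  cat("  panel rows:", nrow(x$panel), "(",
      sum(!x$panel$observed), "unobserved )\n")
  cat("  traits    :", paste(unique(x$panel$trait), collapse = ", "), "\n")
  invisible(x)
}

#' Apply design- and attrition-based missingness
#'
#' Marks panel cells unobserved according to the cohort design and the
#' configured attrition rates: older-cohort participants have no age-11 or
#' age-14 assessments (they enter the study at 17); whole study visits are
#' lost at the pair level with the configured retention rates (ages 14 and
#' 17 for the younger cohort, whose intake was age 11; ages 21 and 24 for
#' everyone); teacher reports are additionally available only for a
#' per-person fraction of retained visits; and attainment is missing for a
#' small fraction of participants.  All mechanisms are Bernoulli draws
#' (missing completely at random).  Unobserved cells have `value`/
#' `ea_category` set to `NA`.
#'
#' @param data A fully observed `panel_data` from [simulate_cohort()].
#' @param config A [cohort_config()]; defaults to the one stored in `data`.
#' @param seed Integer seed for the attrition draws.
#' @return The `panel_data` with updated `observed` flags and masked values.
#' @export
apply_missingness <- function(data, config = data$config,
                              seed = config$seed + 1L) {
  stopifnot(inherits(data, "panel_data"))
  rates <- unlist(config$missingness)
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]")
  if (nrow(data$persons) == 0) return(data)
  set.seed(seed)

  persons <- data$persons
  panel <- data$panel
  n <- nrow(persons)
  fam_ids <- unique(persons$family_id)
  ret <- config$missingness$retention

  ## pair-level visit retention; age-11 and (for the older cohort) age-17
  ## visits are intake assessments and always present
  visit_ages <- c("14", "17", "21", "24")
  keep <- sapply(visit_ages, function(a)
    runif(length(fam_ids)) < ret[[a]])
  rownames(keep) <- as.character(fam_ids)

  fam_of <- persons$family_id[match(panel$person_id, persons$person_id)]
  coh_of <- persons$cohort[match(panel$person_id, persons$person_id)]
  occ_chr <- as.character(panel$occasion)

  obs <- rep(TRUE, nrow(panel))
  ## design: older cohort enters at 17
  obs[coh_of == "older" & panel$occasion %in% c(11L, 14L)] <- FALSE
  ## attrition at followup visits (intake visits exempt)
  for (a in c("14", "17", "21", "24")) {
    lost_fam <- as.character(fam_ids)[!keep[, a]]
    hit <- occ_chr == a & as.character(fam_of) %in% lost_fam
    if (a %in% c("14", "17")) hit <- hit & coh_of == "younger"
    obs[hit] <- FALSE
  }
  ## teacher-report availability (person-level, on top of retained visits)
  tav <- config$missingness$teacher
  for (a in names(tav)) {
    miss_person <- persons$person_id[runif(n) >= tav[[a]]]
    obs[panel$trait == "motiv_teacher" & occ_chr == a &
          panel$person_id %in% miss_person] <- FALSE
  }

  panel$observed <- obs
  panel$value[!obs] <- NA_real_
  data$panel <- panel

  ea_obs <- runif(n) >= config$missingness$ea_missing
  data$attainment$observed <- ea_obs
  data$attainment$ea_category[!ea_obs] <- NA_integer_
  data
}
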