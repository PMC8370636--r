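test_that("empty cohort yields empty tables with the full schema", {
  dat <- simulate_cohort(cohort_config(n_families = 0))
  expect_s3_class(dat, "panel_data")
  expect_equal(nrow(dat$persons), 0)
  expect_equal(nrow(dat$panel), 0)
  expect_true(all(c("person_id", "trait", "occasion", "informant",
                    "value", "observed") %in% names(dat$panel)))
  expect_true(all(c("pgs_smoking", "pgs_edu", "zygosity", "cohort",
                    paste0("pc", 1:5)) %in% names(dat$persons)))
})

test_that("MZ co-twins carry identical polygenic scores, DZ do not", {
  dat <- small_cohort()
  p <- dplyr::arrange(dat$persons, family_id)
  t1 <- p[seq(1, nrow(p), 2), ]
  t2 <- p[seq(2, nrow(p), 2), ]
  mz <- t1$zygosity == "MZ"
  expect_true(all(t1$pgs_smoking[mz] == t2$pgs_smoking[mz]))
  expect_true(all(t1$pgs_edu[mz] == t2$pgs_edu[mz]))
  expect_true(all(t1$pgs_smoking[!mz] != t2$pgs_smoking[!mz]))
  ## DZ within-pair correlation near 0.5
  expect_gt(cor(t1$pgs_smoking[!mz], t2$pgs_smoking[!mz]), 0.25)
  expect_lt(cor(t1$pgs_smoking[!mz], t2$pgs_smoking[!mz]), 0.75)
})

test_that("same seed reproduces the dataset byte-identically, different seeds differ in values only", {
  cfg <- cohort_config(n_families = 60)
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  c <- simulate_cohort(cfg, seed = 43)
  expect_identical(a$panel, b$panel)
  expect_identical(a$persons, b$persons)
  expect_identical(names(a$panel), names(c$panel))
  expect_identical(dim(a$persons), dim(c$persons))
  expect_false(isTRUE(all.equal(a$panel$value, c$panel$value)))
})

test_that("invalid configurations are rejected with a diagnostic naming the block", {
  expect_error(cohort_config(prop_mz = 1.4), "fractions")
  expect_error(cohort_config(familial_a = 0.8, familial_c = 0.5),
               "familial")
  cfg <- cohort_config(n_families = 10)
  cfg$ri_resid_cov[1, 2] <- 0.999
  cfg$ri_resid_cov[2, 1] <- 0.999
  expect_error(validate_cohort_config(cfg), "ri_resid_cov")
  cfg2 <- cohort_config(n_families = 10)
  cfg2$ea_model$thresholds <- sort(cfg2$ea_model$thresholds,
                                   decreasing = TRUE)
  expect_error(validate_cohort_config(cfg2), "thresholds")
  cfg3 <- cohort_config(n_families = 400)
  cfg3$missingness$ea_missing <- 1.5
  expect_error(apply_missingness(small_cohort(), cfg3), "\\[0, 1\\]")
})

test_that("generated composites match the configured population moments", {
  ## moderate n; tolerances at ~4 Monte-Carlo SEs with a design effect of 2
  ## for twin clustering
  dat <- simulate_cohort(cohort_config(n_families = 4000), seed = 7)
  n <- nrow(dat$persons)
  d <- cohort_descriptives(dat)
  tg <- reference_targets()$descriptives
  m <- merge(as.data.frame(d), as.data.frame(tg),
             by = c("trait", "occasion"), suffixes = c("", "_target"))
  tol_mean <- 4 * sqrt(2) * m$sd_target / sqrt(n)
  expect_true(all(abs(m$mean - m$mean_target) < tol_mean))
  expect_true(all(abs(m$sd - m$sd_target) / m$sd_target < 0.05))
  ## lag-1 stabilities of the academic traits
  ac <- m[!is.na(m$r_lag1_target), ]
  expect_true(all(abs(ac$r_lag1 - ac$r_lag1_target) < 0.05))
})

test_that("MZ twins are more alike than DZ twins on stable traits when A > 0", {
  dat <- simulate_cohort(cohort_config(n_families = 4000), seed = 8,
                         keep_latent = TRUE)
  lat <- dplyr::left_join(dat$latent,
                          dat$persons[, c("person_id", "family_id",
                                          "zygosity")],
                          by = "person_id")
  lat <- dplyr::arrange(lat, family_id)
  for (tr in c("eta_gpa", "eta_discipline", "eta_cigs_per_day")) {
    v1 <- lat[[tr]][seq(1, nrow(lat), 2)]
    v2 <- lat[[tr]][seq(2, nrow(lat), 2)]
    mz <- lat$zygosity[seq(1, nrow(lat), 2)] == "MZ"
    expect_gt(cor(v1[mz], v2[mz]), cor(v1[!mz], v2[!mz]))
  }
})

test_that("lag-1 autocorrelation grows with rho and with the stable-trait share", {
  acor <- function(psi, theta, rho) {
    S <- implied_moments(ripm_params(c(0, 0, 0), psi, theta, rho))$cov
    S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  }
  rhos <- seq(0, 0.9, by = 0.15)
  vals <- vapply(rhos, function(r) acor(1, c(1, 1, 1), c(r, r)), 0)
  expect_true(all(diff(vals) > 0))
  shares <- vapply(c(4, 1, 0.25, 0.05),
                   function(th) acor(1, rep(th, 3), c(0, 0)), 0)
  expect_true(all(diff(shares) > 0))
  expect_gt(acor(1, rep(1e-9, 3), c(0, 0)), 1 - 1e-6)
})

test_that("missingness honours cohort design and configured rates", {
  cfg <- cohort_config(n_families = 3000)
  dat0 <- simulate_cohort(cfg, seed = 10)
  dat <- apply_missingness(dat0, seed = 11)
  panel <- dplyr::left_join(dat$panel,
                            dat$persons[, c("person_id", "cohort")],
                            by = "person_id")
  old <- panel[panel$cohort == "older" & panel$occasion %in% c(11, 14), ]
  expect_true(all(!old$observed))
  expect_true(all(is.na(old$value)))
  ## retention at 14 among younger-cohort GPA composites
  y14 <- panel[panel$cohort == "younger" & panel$occasion == 14 &
                 panel$trait == "gpa" & panel$informant == "composite", ]
  p14 <- mean(y14$observed)
  expect_lt(abs(p14 - 0.914), 4 * sqrt(2) * sqrt(0.914 * 0.086 / nrow(y14)))
  ## teacher availability on top of visit retention at age 11
  t11 <- panel[panel$cohort == "younger" & panel$occasion == 11 &
                 panel$trait == "motiv_teacher" &
                 panel$informant == "composite", ]
  expect_lt(abs(mean(t11$observed) - 0.699),
            4 * sqrt(0.699 * 0.301 / nrow(t11)))
  ## attainment missingness
  expect_lt(abs(mean(!dat$attainment$observed) - 0.079),
            4 * sqrt(2) * sqrt(0.079 * 0.921 / nrow(dat$attainment)))
  ## no-missingness limit leaves the dataset unchanged
  cfg0 <- cohort_config(n_families = 50, prop_younger_cohort = 1,
                        missingness = list(
                          retention = c("14" = 1, "17" = 1, "21" = 1,
                                        "24" = 1),
                          teacher = c("11" = 1, "14" = 1, "17" = 1),
                          ea_missing = 0))
  d0 <- simulate_cohort(cfg0, seed = 3)
  d1 <- apply_missingness(d0, seed = 4)
  expect_identical(d0$panel, d1$panel)
  expect_identical(d0$attainment$ea_category, d1$attainment$ea_category)
})

test_that("visit attrition removes both twins of a pair together", {
  dat <- apply_missingness(simulate_cohort(
    cohort_config(n_families = 800), seed = 21), seed = 22)
  g14 <- dat$panel[dat$panel$trait == "gpa" & dat$panel$occasion == 14 &
                     dat$panel$informant == "composite", ]
  g14 <- dplyr::left_join(g14,
                          dat$persons[, c("person_id", "family_id")],
                          by = "person_id")
  per_fam <- tapply(g14$observed, g14$family_id, mean)
  expect_true(all(per_fam %in% c(0, 1)))
})

test_that("long export round-trips losslessly and wide export names trait_age columns", {
  dat <- apply_missingness(simulate_cohort(
    cohort_config(n_families = 30), seed = 5), seed = 6)
  tmp <- tempfile(fileext = ".csv")
  export_panel(dat, tmp, layout = "long")
  back <- read_panel(tmp)
  expect_equal(as.data.frame(back$panel), as.data.frame(dat$panel))
  expect_equal(as.data.frame(back$persons), as.data.frame(dat$persons))
  expect_equal(as.data.frame(back$attainment),
               as.data.frame(dat$attainment))
  ## unobserved cells written as the sentinel
  lines <- readLines(tmp)
  expect_true(any(grepl(",NA,", lines, fixed = TRUE)))
  tmpw <- tempfile(fileext = ".csv")
  export_panel(dat, tmpw, layout = "wide")
  wide <- readr::read_csv(tmpw, show_col_types = FALSE)
  expect_true(all(c("gpa_11", "gpa_14", "gpa_17", "cigs_per_day_24")
                  %in% names(wide)))
  expect_error(export_panel(simulate_cohort(cohort_config(n_families = 0)),
                            tempfile()), "empty")
  expect_error(export_panel(dat, tmp, layout = "sideways"))
})
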