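#' Published calibration targets for the default synthetic cohort
#'
#' The default configuration of [cohort_config()] is calibrated to the
#' published descriptive statistics of a large U.S. twin-family cohort in
#' which academic adjustment (grade point average, self/parent- and
#' teacher-reported academic motivation, disciplinary problems) was assessed
#' at ages 11, 14 and 17, cigarettes per day at ages 14-24, and educational
#' attainment in adulthood.  This function returns those targets as plain
#' tables so that the calibration is inspectable and so that reporting
#' helpers ([mean_lag1_autocorrelation()], [percent_attenuation()],
#' [correlation_summary()]) can be applied to the published numbers
#' directly.
#'
#' @return A named list:
#' \describe{
#'   \item{descriptives}{tibble of per-trait, per-occasion means, SDs, Ns
#'     and the correlations with earlier occasions (`r_lag1` is the
#'     correlation with the immediately preceding occasion, `r_lag2` with
#'     the occasion two steps back).}
#'   \item{informant_r}{tibble of inter-informant correlations used to set
#'     informant noise (twin vs mother for GPA, self vs mother for
#'     motivation, twin vs mother for discipline items, teacher vs
#'     self/parent composite).}
#'   \item{ri_betas}{tibble of standardized regression coefficients from
#'     each polygenic score to each trait's random intercept, in the
#'     one-PGS and two-PGS conditional models.}
#'   \item{mediation_corr}{named 8 x 8 correlation matrix among the two
#'     polygenic scores, the five random-intercept factor scores, and
#'     age-adjusted educational attainment.}
#'   \item{path_truths}{tibble of standardized mediation-model paths
#'     (PGS -> random intercept, random intercept -> attainment, and the
#'     PGS -> attainment direct effects).}
#'   \item{ea_shares}{tibble of the six educational-attainment category
#'     labels and their published percentage shares.}
#'   \item{ea_age_r}{published correlation between age at report and the
#'     6-category attainment variable (0.27).}
#' }
#' @seealso [cohort_config()], which turns these targets into generator
#'   parameters.
#' @export
#' @examples
#' tg <- reference_targets()
#' tg$descriptives
#' # mean lag-1 stability of teacher-rated motivation:
#' mean_lag1_autocorrelation(c(0.58, 0.58))
reference_targets <- function() {
  descriptives <- tibble::tribble(
    ~trait,          ~occasion, ~mean, ~sd,  ~n,    ~r_lag1, ~r_lag2,
    "gpa",            11,        3.10,  0.66, 2492,  NA,      NA,
    "gpa",            14,        3.06,  0.79, 2357,  0.64,    NA,
    "gpa",            17,        3.02,  0.77, 3449,  0.73,    0.56,
    "motiv_sp",       11,       20.89,  2.50, 2502,  NA,      NA,
    "motiv_sp",       14,       19.83,  2.94, 2335,  0.47,    NA,
    "motiv_sp",       17,       19.76,  3.08, 3412,  0.62,    0.41,
    "motiv_teacher",  11,       19.87,  3.13, 1754,  NA,      NA,
    "motiv_teacher",  14,       19.64,  3.40, 1808,  0.58,    NA,
    "motiv_teacher",  17,       19.67,  3.42, 2249,  0.58,    0.53,
    "discipline",     11,        0.00,  0.61, 2429,  NA,      NA,
    "discipline",     14,        0.00,  0.80, 2357,  0.25,    NA,
    "discipline",     17,        0.00,  0.75, 3512,  0.48,    0.25,
    "cigs_per_day",   14,        0.53,  1.29, 2334,  NA,      NA,
    "cigs_per_day",   17,        1.36,  1.86, 3444,  NA,      NA,
    "cigs_per_day",   21,        2.00,  2.06, 2698,  NA,      NA,
    "cigs_per_day",   24,        1.79,  2.05, 3258,  NA,      NA
  )

  informant_r <- tibble::tribble(
    ~trait,          ~pair,                  ~r,
    "gpa",           "twin_mother",          0.79,
    "motiv_sp",      "self_mother",          0.51,
    "discipline",    "twin_mother",          0.62,
    "motiv_teacher", "teacher_self_parent",  0.55
  )

  ri_betas <- tibble::tribble(
    ~trait,          ~pgs,          ~beta_1pgs, ~beta_2pgs,
    "gpa",           "pgs_smoking", -0.20,      -0.13,
    "gpa",           "pgs_edu",      0.35,       0.32,
    "motiv_sp",      "pgs_smoking", -0.22,      -0.19,
    "motiv_sp",      "pgs_edu",      0.17,       0.12,
    "motiv_teacher", "pgs_smoking", -0.21,      -0.15,
    "motiv_teacher", "pgs_edu",      0.28,       0.25,
    "discipline",    "pgs_smoking",  0.28,       0.26,
    "discipline",    "pgs_edu",     -0.15,      -0.09,
    "cigs_per_day",  "pgs_smoking",  0.20,       0.18,
    "cigs_per_day",  "pgs_edu",     -0.14,      -0.10,
    "attainment",    "pgs_smoking", -0.19,      -0.14,
    "attainment",    "pgs_edu",      0.26,       0.23
  )

  vars <- c("pgs_smoking", "pgs_edu", "ri_gpa", "ri_motiv_sp",
            "ri_motiv_teacher", "ri_discipline", "ri_cigs_per_day",
            "attainment")
  R <- diag(8)
  dimnames(R) <- list(vars, vars)
  lower <- list(
    c("pgs_edu", "pgs_smoking", -0.23),
    c("ri_gpa", "pgs_smoking", -0.14), c("ri_gpa", "pgs_edu", 0.24),
    c("ri_motiv_sp", "pgs_smoking", -0.15), c("ri_motiv_sp", "pgs_edu", 0.11),
    c("ri_motiv_sp", "ri_gpa", 0.58),
    c("ri_motiv_teacher", "pgs_smoking", -0.17),
    c("ri_motiv_teacher", "pgs_edu", 0.21),
    c("ri_motiv_teacher", "ri_gpa", 0.67),
    c("ri_motiv_teacher", "ri_motiv_sp", 0.59),
    c("ri_discipline", "pgs_smoking", 0.16), c("ri_discipline", "pgs_edu", -0.08),
    c("ri_discipline", "ri_gpa", -0.38), c("ri_discipline", "ri_motiv_sp", -0.47),
    c("ri_discipline", "ri_motiv_teacher", -0.51),
    c("ri_cigs_per_day", "pgs_smoking", 0.20), c("ri_cigs_per_day", "pgs_edu", -0.14),
    c("ri_cigs_per_day", "ri_gpa", -0.30), c("ri_cigs_per_day", "ri_motiv_sp", -0.36),
    c("ri_cigs_per_day", "ri_motiv_teacher", -0.38),
    c("ri_cigs_per_day", "ri_discipline", 0.37),
    c("attainment", "pgs_smoking", -0.20), c("attainment", "pgs_edu", 0.26),
    c("attainment", "ri_gpa", 0.52), c("attainment", "ri_motiv_sp", 0.39),
    c("attainment", "ri_motiv_teacher", 0.51),
    c("attainment", "ri_discipline", -0.35),
    c("attainment", "ri_cigs_per_day", -0.30)
  )
  for (e in lower) {
    R[e[1], e[2]] <- R[e[2], e[1]] <- as.numeric(e[3])
  }

  path_truths <- tibble::tribble(
    ~pgs,          ~target,            ~beta,
    "pgs_smoking", "ri_gpa",           -0.09,
    "pgs_smoking", "ri_motiv_sp",      -0.13,
    "pgs_smoking", "ri_motiv_teacher", -0.13,
    "pgs_smoking", "ri_discipline",     0.15,
    "pgs_smoking", "ri_cigs_per_day",   0.18,
    "pgs_smoking", "attainment_direct", -0.07,
    "pgs_edu",     "ri_gpa",            0.22,
    "pgs_edu",     "ri_motiv_sp",       0.09,
    "pgs_edu",     "ri_motiv_teacher",  0.19,
    "pgs_edu",     "ri_discipline",    -0.05,
    "pgs_edu",     "ri_cigs_per_day",  -0.10,
    "pgs_edu",     "attainment_direct", 0.11,
    "outcome",     "b_ri_gpa",          0.28,
    "outcome",     "b_ri_motiv_sp",     0.03,
    "outcome",     "b_ri_motiv_teacher", 0.21,
    "outcome",     "b_ri_discipline",  -0.08,
    "outcome",     "b_ri_cigs_per_day", -0.05
  )

  ea_shares <- tibble::tribble(
    ~category, ~label,                                      ~share,
    1L, "less than high school diploma",                     9.5,
    2L, "high school graduate or GED",                       9.8,
    3L, "vocational degree, some college, or associate's",  30.5,
    4L, "bachelor's degree",                                31.9,
    5L, "master's level degree",                             8.8,
    6L, "PhD or other advanced professional degree",         4.2
  )

  list(
    descriptives = descriptives,
    informant_r = informant_r,
    ri_betas = ri_betas,
    mediation_corr = R,
    path_truths = path_truths,
    ea_shares = ea_shares,
    ea_age_r = 0.27
  )
}
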