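## Instrument coding for the analysis variables: multi-informant
## composites, either-informant discipline items, cigarettes-per-day
## binning, and age-residualized educational attainment.

check_items <- function(x, n_items, lo, hi, what) {
  if (is.null(x)) return(NULL)
  x <- as.numeric(x)
  if (length(x) != n_items)
    stop(what, " must have ", n_items, " items, got ", length(x))
  bad <- x[!is.na(x) & (x < lo | x > hi)]
  if (length(bad))
    stop(what, " values outside [", lo, ", ", hi, "]: ",
         paste(bad, collapse = ", "))
  x
}

#' Grade point average composite from twin and mother reports
#'
#' Each informant reports the typical grade (A = 4 down to F = 0) in four
#' class subjects (reading/English, math, social studies/history, science).
#' The composite is the mean over subjects within informant, then the mean
#' over available informants; with one informant missing the other's
#' subject mean passes through.
#'
#' @param twin,mother Numeric vectors of 4 subject grades on 0-4, or `NULL`
#'   for a missing informant.
#' @return A single composite GPA in `[0, 4]` (`NA` if both missing).
#' @export
#' @examples
#' compose_gpa(c(4, 3, 3, 2), c(2, 3, 3, 4))  # 3.0
compose_gpa <- function(twin = NULL, mother = NULL) {
  twin <- check_items(twin, 4, 0, 4, "twin grades")
  mother <- check_items(mother, 4, 0, 4, "mother grades")
  means <- c(if (!is.null(twin)) mean(twin, na.rm = TRUE),
             if (!is.null(mother)) mean(mother, na.rm = TRUE))
  means <- means[is.finite(means)]
  if (!length(means)) return(NA_real_)
  mean(means)
}

#' Academic motivation composites
#'
#' The 6-item school-attitudes scale is scored as the sum of items within
#' informant, then the mean across informants: self and mother reports for
#' `compose_motivation()`, and 1-3 teacher reports for
#' `compose_motivation_teacher()` (the mean across teachers whenever more
#' than one rating is available).  Items are assumed to be on a 1-4
#' response scale, giving a composite range of 6-24.
#'
#' @param self,mother Numeric vectors of 6 item responses, or `NULL`.
#' @param reports For the teacher variant, a list of 1-3 item vectors.
#' @return The composite score (`NA` if no informant available).
#' @export
#' @examples
#' compose_motivation(rep(22 / 6, 6), rep(3, 6))  # (22 + 18) / 2 = 20
compose_motivation <- function(self = NULL, mother = NULL) {
  self <- check_items(self, 6, 1, 4, "self items")
  mother <- check_items(mother, 6, 1, 4, "mother items")
  sums <- c(if (!is.null(self)) sum(self),
            if (!is.null(mother)) sum(mother))
  sums <- sums[is.finite(sums)]
  if (!length(sums)) return(NA_real_)
  mean(sums)
}

#' @rdname compose_motivation
#' @export
compose_motivation_teacher <- function(reports) {
  if (!is.list(reports)) reports <- list(reports)
  if (length(reports) < 1 || length(reports) > 3)
    stop("1 to 3 teacher reports expected, got ", length(reports))
  sums <- vapply(reports, function(r)
    sum(check_items(r, 6, 1, 4, "teacher items")), numeric(1))
  mean(sums)
}

#' Combine discipline items across informants ("either-informant" rule)
#'
#' Six school-discipline events are rated 0 = never, 1 = once or twice,
#' 2 = two or more times by twin and mother; an event is considered present
#' if reported by either informant.  The combined item is the elementwise
#' maximum of the two reports, which honours either-report presence while
#' preserving the 0/1/2 grading.  A missing informant's vector passes
#' through unchanged.
#'
#' @param twin,mother Numeric vectors of 6 items in `{0, 1, 2}`, or `NULL`.
#' @return Combined 6-item vector.
#' @export
code_discipline_items <- function(twin = NULL, mother = NULL) {
  twin <- check_items(twin, 6, 0, 2, "twin discipline items")
  mother <- check_items(mother, 6, 0, 2, "mother discipline items")
  chk <- function(x) {
    if (!is.null(x) && any(!is.na(x) & !x %in% 0:2))
      stop("discipline items must be 0, 1 or 2")
    x
  }
  twin <- chk(twin); mother <- chk(mother)
  if (is.null(twin)) return(mother)
  if (is.null(mother)) return(twin)
  pmax(twin, mother, na.rm = TRUE)
}

#' Convert raw cigarettes per day to the 0-6 scale
#'
#' Free responses (average cigarettes/day, or equivalent nicotine use) are
#' binned to a 7-point scale with fixed endpoints: 0 = no use and
#' 6 = twenty or more per day.  Default interior bins: 1 = less than one
#' per day, 2 = 1-5, 3 = 6-10, 4 = 11-15, 5 = 16-19.  The map is monotone
#' non-decreasing in the raw count; the bin table can be overridden.
#'
#' @param raw Numeric vector of cigarettes/day, `>= 0`.
#' @param bins Optional increasing numeric vector of 6 upper-inclusive
#'   break points `b1 < ... < b6`; category `k` covers
#'   `(b_k, b_{k+1}]` with category 0 reserved for exactly zero use and 6
#'   for anything above `b6`.  Default `c(0, 0.999, 5, 10, 15, 19.999)`.
#' @return Integer vector of 0-6 codes.
#' @export
#' @examples
#' code_cigarettes(c(0, 0.5, 10, 25))  # 0 1 3 6
code_cigarettes <- function(raw, bins = NULL) {
  if (any(!is.na(raw) & raw < 0)) stop("cigarettes/day cannot be negative")
  if (is.null(bins)) bins <- c(0, 0.999, 5, 10, 15, 19.999)
  if (length(bins) != 6 || any(diff(bins) <= 0))
    stop("`bins` must be 6 strictly increasing break points")
  out <- findInterval(raw, bins, left.open = TRUE)
  out[!is.na(raw) & raw == 0] <- 0L
  as.integer(out)
}

#' Age-residualized educational attainment
#'
#' Regresses the 6-category attainment variable on age at report by least
#' squares over the observed records and stores the unstandardized
#' residual, which is the attainment score used in all downstream models.
#'
#' @param records Data frame with columns `ea_category` (1-6, may be `NA`)
#'   and `age_at_report`.
#' @return The input with an `ea_residual` column added (`NA` where the
#'   category is unobserved).
#' @export
residualize_attainment <- function(records) {
  stopifnot(all(c("ea_category", "age_at_report") %in% names(records)))
  ok <- !is.na(records$ea_category) & !is.na(records$age_at_report)
  if (sum(ok) < 3)
    stop("need at least 3 observed (category, age) records")
  if (sd(records$age_at_report[ok]) == 0)
    stop("all ages identical: age regression is undefined")
  fit <- lm(ea_category ~ age_at_report, data = records[ok, ])
  records$ea_residual <- NA_real_
  records$ea_residual[ok] <- resid(fit)
  records
}
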