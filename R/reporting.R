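#' Round half away from zero
#'
#' Two-decimal "round half up" (0.545 prints as 0.55), matching the
#' conventional rendering of descriptive tables; base R's `round()` rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  ## small epsilon absorbs binary representation error (0.545 * 100 is
  ## slightly below 54.5 in double precision)
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Mean lag-1 autocorrelation
#'
#' The arithmetic mean of the adjacent-occasion (lag-1) correlations only;
#' correlations at longer lags are excluded.  This is the "mean
#' autocorrelation" summary reported for each longitudinal trait.
#'
#' @param corrs Numeric vector of adjacent-occasion correlations (e.g.
#'   `c(r_11_14, r_14_17)`).
#' @return Their mean.
#' @export
#' @examples
#' mean_lag1_autocorrelation(c(0.47, 0.62))  # 0.545, prints as .55
mean_lag1_autocorrelation <- function(corrs) {
  corrs <- corrs[!is.na(corrs)]
  if (!length(corrs)) stop("no lag-1 correlations supplied")
  mean(corrs)
}

#' Percent attenuation between one- and two-predictor coefficients
#'
#' `(|beta_1pgs| - |beta_2pgs|) / |beta_1pgs| * 100`: the percentage by
#' which a polygenic score's standardized effect shrinks when the other
#' polygenic score is added to the model.  Invariant to the sign
#' convention of the coefficients; negative values indicate suppression
#' (the adjusted effect grew).
#'
#' @param beta_1pgs Coefficient from the one-predictor model (nonzero).
#' @param beta_2pgs Coefficient from the two-predictor model.
#' @return Percent reduction.
#' @export
#' @examples
#' percent_attenuation(-0.20, -0.13)  # 35
percent_attenuation <- function(beta_1pgs, beta_2pgs) {
  if (any(beta_1pgs == 0))
    stop("percent attenuation is undefined for beta_1pgs = 0")
  (abs(beta_1pgs) - abs(beta_2pgs)) / abs(beta_1pgs) * 100
}

#' Summaries of absolute correlations in a matrix block
#'
#' Selects the block of a named correlation matrix given by `rows` x
#' `cols` and summarises the absolute values of its off-diagonal entries
#' (diagonal/self-pairs are excluded; when the row and column sets
#' overlap, each unordered pair is counted once).
#'
#' @param R Named square correlation matrix.
#' @param rows,cols Character vectors of row/column names.
#' @param mode One of `"mean_abs"`, `"max_abs"`, `"min_abs"`.
#' @return The summary value.
#' @export
correlation_summary <- function(R, rows, cols,
                                mode = c("mean_abs", "max_abs",
                                         "min_abs")) {
  mode <- match.arg(mode)
  stopifnot(all(rows %in% rownames(R)), all(cols %in% colnames(R)))
  vals <- c()
  seen <- character()
  for (r in rows) for (cl in cols) {
    if (r == cl) next
    key <- paste(sort(c(r, cl)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    vals <- c(vals, abs(R[r, cl]))
  }
  if (!length(vals)) stop("empty correlation block")
  switch(mode, mean_abs = mean(vals), max_abs = max(vals),
         min_abs = min(vals))
}

fmt2 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.2f", round_half_up(x, 2)))
}

#' Render result tables
#'
#' Formats descriptives, conditional RI-PM coefficients and mediation
#' decompositions as tidy tables with two-decimal half-up rounding and a
#' `significant` marker column, and optionally writes them as CSV and
#' GitHub-flavoured Markdown.  Missing inputs yield a partial report.
#'
#' @param descriptives Optional tibble like
#'   `reference_targets()$descriptives` or the output of
#'   [cohort_descriptives()].
#' @param ripm_results Optional tibble with columns `trait, pgs, model,
#'   estimate` and optionally `ci_lower, ci_upper, p`.
#' @param mediation Optional [decompose_effects()] tibble.
#' @param out_dir Optional directory; when given, each table is written as
#'   `<name>.csv` and `<name>.md`.
#' @return Named list of formatted tibbles (invisibly when writing).
#' @export
render_tables <- function(descriptives = NULL, ripm_results = NULL,
                          mediation = NULL, out_dir = NULL) {
  out <- list()
  if (!is.null(descriptives)) {
    d <- descriptives
    num <- vapply(d, is.numeric, TRUE) & !names(d) %in% c("occasion", "n")
    d[num] <- lapply(d[num], round_half_up)
    out$descriptives <- d
  }
  if (!is.null(ripm_results)) {
    r <- ripm_results
    if (all(c("ci_lower", "ci_upper") %in% names(r))) {
      p <- if ("p" %in% names(r)) r$p else rep(NA_real_, nrow(r))
      r$significant <- vapply(seq_len(nrow(r)), function(i) {
        if (is.na(r$ci_lower[i])) return(NA)
        isTRUE(flag_significance(r$estimate[i],
                                 c(r$ci_lower[i], r$ci_upper[i]),
                                 p = if (is.na(p[i])) NULL else p[i],
                                 se = (r$ci_upper[i] - r$ci_lower[i]) /
                                   (2 * qnorm(0.975))))
      }, NA)
    }
    num <- vapply(r, is.numeric, TRUE)
    r[num] <- lapply(r[num], round_half_up)
    out$ripm <- r
  }
  if (!is.null(mediation)) {
    m <- mediation
    num <- vapply(m, is.numeric, TRUE)
    m[num] <- lapply(m[num], function(x) round_half_up(x, 3))
    out$mediation <- m
  }
  if (!length(out)) {
    out <- list(descriptives = tibble::tibble())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       na = "")
      writeLines(markdown_table(out[[nm]]),
                 file.path(out_dir, paste0(nm, ".md")))
    }
    return(invisible(out))
  }
  out
}

markdown_table <- function(d) {
  if (!nrow(d)) return("| (empty) |")
  cells <- vapply(d, function(col) {
    if (is.numeric(col)) fmt2(col) else as.character(col)
  }, character(nrow(d)))
  cells <- matrix(cells, nrow = nrow(d))
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Descriptive table of a synthetic cohort
#'
#' Per-trait, per-occasion mean, SD and N of the observed composites, plus
#' lag-1 and lag-2 correlations — the shape of a standard longitudinal
#' descriptives table, computable from any `panel_data`.
#'
#' @param data A `panel_data` object.
#' @return Tibble with columns `trait, occasion, mean, sd, n, r_lag1,
#'   r_lag2`.
#' @export
cohort_descriptives <- function(data) {
  comp <- build_composites(data)
  wide <- tidyr::pivot_wider(comp, id_cols = "person_id",
                             names_from = c("trait", "occasion"),
                             values_from = "value")
  rows <- list()
  for (tr in unique(comp$trait)) {
    occs <- sort(unique(comp$occasion[comp$trait == tr]))
    for (i in seq_along(occs)) {
      col <- wide[[paste0(tr, "_", occs[i])]]
      r1 <- if (i > 1)
        cor(col, wide[[paste0(tr, "_", occs[i - 1])]],
            use = "pairwise.complete.obs") else NA_real_
      r2 <- if (i > 2)
        cor(col, wide[[paste0(tr, "_", occs[i - 2])]],
            use = "pairwise.complete.obs") else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        trait = tr, occasion = occs[i],
        mean = mean(col, na.rm = TRUE), sd = sd(col, na.rm = TRUE),
        n = sum(!is.na(col)), r_lag1 = r1, r_lag2 = r2)
    }
  }
  dplyr::bind_rows(rows)
}
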