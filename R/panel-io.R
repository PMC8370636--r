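#' Build composite scores from informant-level panel rows
#'
#' Collapses the long panel to one composite value per (person, trait,
#' occasion): the mean over available informant reports for multi-informant
#' traits (any pre-computed `composite` rows are recomputed from informants
#' when informant rows are observed, and used as-is otherwise), and the 0-6
#' coded scale for cigarettes per day via [code_cigarettes()].  A cell is
#' missing only when no informant observed it.
#'
#' @param data A `panel_data` object or a long panel tibble with columns
#'   `person_id, trait, occasion, informant, value, observed`.
#' @param cig_bins Optional override of the cigarettes-per-day bin table
#'   passed to [code_cigarettes()].
#' @return Tibble with columns `person_id, trait, occasion, value`.
#' @export
build_composites <- function(data, cig_bins = NULL) {
  panel <- if (inherits(data, "panel_data")) data$panel else data
  obs <- panel[panel$observed & !is.na(panel$value), ]

  cigs <- obs[obs$trait == "cigs_per_day", ]
  rest <- obs[obs$trait != "cigs_per_day", ]

  inform <- rest[rest$informant != "composite", ]
  comp_only <- rest[rest$informant == "composite", ]
  agg <- dplyr::summarise(
    dplyr::group_by(inform, person_id, trait, occasion),
    value = mean(value), .groups = "drop")
  ## composite rows fill cells with no informant-level data at all
  key <- paste(agg$person_id, agg$trait, agg$occasion)
  fill <- comp_only[!paste(comp_only$person_id, comp_only$trait,
                           comp_only$occasion) %in% key,
                    c("person_id", "trait", "occasion", "value")]
  out <- dplyr::bind_rows(agg, fill)

  if (nrow(cigs)) {
    cig_comp <- tibble::tibble(
      person_id = cigs$person_id, trait = "cigs_per_day",
      occasion = cigs$occasion,
      value = as.numeric(code_cigarettes(cigs$value, bins = cig_bins)))
    out <- dplyr::bind_rows(out, cig_comp)
  }
  dplyr::arrange(out, person_id, trait, occasion)
}

#' Pivot a cohort to one row per person
#'
#' Produces the wide layout used by [fit_ripm()] and the mediation stage:
#' one row per person with a `<trait>_<occasion>` column per composite
#' (e.g. `gpa_11`), joined with the person covariates and attainment.
#'
#' @param data A `panel_data` object.
#' @inheritParams build_composites
#' @return A wide tibble.
#' @export
panel_wide <- function(data, cig_bins = NULL) {
  stopifnot(inherits(data, "panel_data"))
  comp <- build_composites(data, cig_bins = cig_bins)
  wide <- tidyr::pivot_wider(comp,
                             id_cols = "person_id",
                             names_from = c("trait", "occasion"),
                             values_from = "value",
                             names_sep = "_")
  out <- dplyr::left_join(data$persons, wide, by = "person_id")
  dplyr::left_join(out,
                   data$attainment[, c("person_id", "ea_category",
                                       "age_at_report")],
                   by = "person_id")
}

#' Export / read a cohort as delimited text
#'
#' The long layout is one row per (person, trait, occasion, informant)
#' measurement joined with the person covariates and attainment record; it
#' round-trips losslessly through [read_panel()].  The wide layout is the
#' [panel_wide()] table (composites only).  Unobserved cells are written as
#' the missing sentinel.
#'
#' @param data A `panel_data` object.
#' @param path Output file; a `.tsv` extension writes tab-delimited.
#' @param layout `"long"` or `"wide"`.
#' @param na Missing-value sentinel string.
#' @return `path`, invisibly.
#' @export
export_panel <- function(data, path, layout = c("long", "wide"),
                         na = "NA") {
  stopifnot(inherits(data, "panel_data"))
  layout <- match.arg(layout)
  if (nrow(data$persons) == 0 && nrow(data$panel) == 0)
    stop("refusing to export an empty dataset")
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  if (layout == "long") {
    out <- dplyr::left_join(data$panel, data$persons, by = "person_id")
    out <- dplyr::left_join(
      out, dplyr::rename(data$attainment, ea_observed = observed),
      by = "person_id")
  } else {
    out <- panel_wide(data)
  }
  readr::write_delim(out, path, delim = delim, na = na)
  invisible(path)
}

#' @rdname export_panel
#' @export
read_panel <- function(path, na = "NA") {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, na = na,
                           show_col_types = FALSE, progress = FALSE)
  person_cols <- c("family_id", "person_id", "zygosity", "sex", "cohort",
                   paste0("pc", 1:5), "pgs_smoking", "pgs_edu",
                   "age_at_last_assessment")
  persons <- dplyr::distinct(raw[, person_cols])
  panel <- raw[, c("person_id", "trait", "occasion", "informant",
                   "value", "observed")]
  panel$occasion <- as.integer(panel$occasion)
  attainment <- dplyr::distinct(
    raw[, c("person_id", "ea_category", "age_at_report", "ea_observed")])
  names(attainment)[4] <- "observed"
  attainment$ea_category <- as.integer(attainment$ea_category)
  structure(list(persons = persons, panel = panel,
                 attainment = attainment, config = NULL),
            class = "panel_data")
}
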