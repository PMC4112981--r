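#' Likelihood grading thresholds
#'
#' The interference ratio `R = apparent_high / decision concentration` is
#' graded `high` when `R >= high`, `possible` when `possible <= R < high`,
#' otherwise `low`.
#'
#' @param high ratio at or above which interference is graded high (default 1:
#'   the interference alone can reach the decision concentration).
#' @param possible ratio at or above which interference is graded possible
#'   (default 0.1: a tenth of the decision concentration).
#' @return named list used by [grade_likelihood()].
#' @export
likelihood_thresholds <- function(high = 1, possible = 0.1) {
  stopifnot(high > possible, possible > 0)
  list(high = high, possible = possible)
}

#' Apparent analyte concentration produced by a cross-reactant
#'
#' `apparent = cross_reactivity_pct / 100 * plasma concentration`, applied to
#' both bounds of a plasma range. An absent lower bound ("up to X") maps to an
#' apparent lower bound of 0.
#'
#' @param cross_reactivity_pct percent cross-reactivity.
#' @param plasma_low,plasma_high plasma range bounds in ng/mL; `plasma_low`
#'   may be `NA`.
#' @return data.frame with `apparent_low`, `apparent_high` (ng/mL). Vectorized.
#' @export
#' @examples
#' apparent_concentration(12.2, NA, 40)   # up to 4.88 ng/mL
apparent_concentration <- function(cross_reactivity_pct, plasma_low, plasma_high) {
  stopifnot(all(cross_reactivity_pct >= 0), all(plasma_high > 0 | is.na(plasma_high)))
  lo <- ifelse(is.na(plasma_low), 0, cross_reactivity_pct / 100 * plasma_low)
  hi <- cross_reactivity_pct / 100 * plasma_high
  data.frame(apparent_low = lo, apparent_high = hi)
}

# decision concentration for one plasma population:
# - populations naming a sex are graded against the matching reference
#   interval(s) (lowest anchor among matches);
# - otherwise the assay's configured clinical decision level is used.
# An interval's anchor is its lower bound when positive, else its upper bound
# (intervals of the form "up to X" or "0 - X" anchor at X).
decision_concentration <- function(population, assay) {
  ivs <- assay$reference_intervals
  if (nrow(ivs) == 0L) stop("assay '", assay$assay_name,
                            "' has no reference intervals")
  fem <- "(^|[^[:alpha:]])(female|females|woman|women)([^[:alpha:]]|$)"
  mal <- "(^|[^[:alpha:]])(male|males|man|men)([^[:alpha:]]|$)"
  anchor <- function(low, high) ifelse(!is.na(low) & low > 0, low, high)
  pop <- tolower(population)
  sel <- NULL
  if (grepl(fem, pop)) {
    sel <- grepl(fem, tolower(ivs$population))
  } else if (grepl(mal, pop)) {
    sel <- grepl(mal, tolower(ivs$population))
  }
  if (!is.null(sel) && any(sel)) {
    return(min(anchor(ivs$low_ng_ml[sel], ivs$high_ng_ml[sel])))
  }
  assay$decision_level
}

#' Grade the clinical likelihood of interference
#'
#' For an interference estimate with plasma data, the grade follows the ratio
#' of the worst-case apparent concentration to a decision concentration: the
#' reference interval matched to the plasma population's sex when one is
#' named, otherwise the assay's configured clinical decision level (see the
#' methods vignette for the packaged values and their rationale). Without
#' plasma data the grade is `unknown`.
#'
#' @param apparent_high worst-case apparent analyte concentration (ng/mL), or
#'   `NA` when no plasma range is available.
#' @param population plasma population label (used for sex matching).
#' @param assay an assay definition (from [load_fixture_panel()] or
#'   [assay_definition()]).
#' @param thresholds see [likelihood_thresholds()].
#' @return one of `"high"`, `"possible"`, `"low"`, `"unknown"`.
#' @export
grade_likelihood <- function(apparent_high, population, assay,
                             thresholds = likelihood_thresholds()) {
  if (is.na(apparent_high)) return("unknown")
  d <- decision_concentration(population, assay)
  r <- apparent_high / d
  if (r >= thresholds$high) "high"
  else if (r >= thresholds$possible) "possible"
  else "low"
}

#' Interference report for an assay panel
#'
#' One estimate per (compound, population) pair with plasma data, plus
#' `unknown`-graded rows for cross-reactive compounds (category above `none`)
#' lacking plasma data. Rows are sorted by descending worst-case apparent
#' concentration, `unknown` rows last.
#'
#' @param assay assay definition.
#' @param records cross-reactivity records for the assay.
#' @param ranges plasma ranges (`compound_name`, `population`, `low_ng_ml`,
#'   `high_ng_ml`, `citation`).
#' @param include_target keep the assay's own target analyte (default drops
#'   it: the target is not an interferent).
#' @param thresholds see [likelihood_thresholds()].
#' @return data.frame of interference estimates.
#' @export
interference_report <- function(assay, records, ranges,
                                include_target = FALSE,
                                thresholds = likelihood_thresholds()) {
  if (!include_target)
    records <- records[records$compound_name != assay$target_compound, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    rr <- ranges[ranges$compound_name == rec$compound_name, , drop = FALSE]
    if (nrow(rr) == 0L) {
      if (rec$category == "none") next
      rows[[length(rows) + 1L]] <- data.frame(
        assay_name = assay$assay_name, compound_name = rec$compound_name,
        population = NA_character_, cross_reactivity_pct = rec$cross_reactivity_pct,
        plasma_low = NA_real_, plasma_high = NA_real_,
        apparent_low = NA_real_, apparent_high = NA_real_,
        likelihood = "unknown", citation = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    app <- apparent_concentration(rec$cross_reactivity_pct, rr$low_ng_ml, rr$high_ng_ml)
    for (j in seq_len(nrow(rr))) {
      rows[[length(rows) + 1L]] <- data.frame(
        assay_name = assay$assay_name, compound_name = rec$compound_name,
        population = rr$population[j],
        cross_reactivity_pct = rec$cross_reactivity_pct,
        plasma_low = rr$low_ng_ml[j], plasma_high = rr$high_ng_ml[j],
        apparent_low = app$apparent_low[j], apparent_high = app$apparent_high[j],
        likelihood = grade_likelihood(app$apparent_high[j], rr$population[j],
                                      assay, thresholds),
        citation = rr$citation[j], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(assay_name = character(0), compound_name = character(0),
                      population = character(0), cross_reactivity_pct = numeric(0),
                      plasma_low = numeric(0), plasma_high = numeric(0),
                      apparent_low = numeric(0), apparent_high = numeric(0),
                      likelihood = character(0), citation = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$apparent_high), -ifelse(is.na(out$apparent_high), 0,
                                                     out$apparent_high)), ]
  rownames(out) <- NULL
  out
}

#' Write an interference report to CSV and/or JSON
#'
#' The JSON form is an array of objects, one per estimate, carrying citation
#' strings verbatim.
#'
#' @param report data.frame from [interference_report()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_interference_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
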