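#' Cross-reactivity categories
#'
#' Percent cross-reactivity is binned into four half-open intervals:
#' strong `[5, Inf)`, weak `[0.5, 5)`, very weak `[0.05, 0.5)`, none
#' `[0, 0.05)`. Every non-negative value falls in exactly one bin.
#'
#' @format character vector of category labels, ordered none < very_weak <
#'   weak < strong.
#' @export
cr_categories <- c("none", "very_weak", "weak", "strong")

# bin edges in percent
cr_bin_edges <- c(0.05, 0.5, 5)

#' Percent cross-reactivity from a spiked-sample measurement
#'
#' `100 * max(0, apparent_spiked - apparent_baseline) / spike_concentration`:
#' the apparent analyte attributable to the spiked test compound, as a
#' percentage of the amount of compound added. Negative baseline-corrected
#' differences (readout noise) are clipped to zero; a message reports how many
#' were clipped.
#'
#' @param spike_concentration ng/mL of test compound added; must be > 0.
#' @param apparent_spiked apparent analyte (ng/mL) in the spiked sample.
#' @param apparent_baseline apparent analyte (ng/mL) in the unadulterated
#'   sample.
#' @return percent cross-reactivity (may exceed 100). Vectorized.
#' @export
#' @examples
#' percent_cross_reactivity(100, 12.2, 0)    # 12.2%
#' percent_cross_reactivity(1000, 2495, 5)   # 249%
percent_cross_reactivity <- function(spike_concentration, apparent_spiked,
                                     apparent_baseline) {
  if (any(!is.finite(spike_concentration)) || any(spike_concentration <= 0))
    stop("spike_concentration must be positive")
  if (any(apparent_spiked < 0) || any(apparent_baseline < 0))
    stop("apparent concentrations must be non-negative")
  delta <- apparent_spiked - apparent_baseline
  n_neg <- sum(delta < 0)
  if (n_neg > 0)
    message("percent_cross_reactivity: clipped ", n_neg,
            " negative baseline-corrected difference(s) to 0")
  100 * pmax(0, delta) / spike_concentration
}

#' Bin percent cross-reactivity into a category
#'
#' @param cr percent cross-reactivity, non-negative. Vectorized.
#' @return factor with levels [cr_categories] (ordered).
#' @export
#' @examples
#' categorize_cr(c(12.2, 4.95, 0.05, 0.049))
categorize_cr <- function(cr) {
  if (any(!is.finite(cr)) || any(cr < 0)) stop("cross-reactivity must be non-negative")
  idx <- findInterval(cr, cr_bin_edges) + 1L
  factor(cr_categories[idx], levels = cr_categories, ordered = TRUE)
}

#' Read spiked-sample measurements from CSV
#'
#' Expected columns: `assay`, `compound`, `spike_ng_ml`,
#' `apparent_spiked_ng_ml`, `apparent_baseline_ng_ml`.
#'
#' @param path CSV path.
#' @return data.frame of measurements.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay", "compound", "spike_ng_ml", "apparent_spiked_ng_ml",
            "apparent_baseline_ng_ml")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("measurement file missing columns: ",
                         paste(miss, collapse = ", "))
  m
}

#' Cross-reactivity records from measurements
#'
#' Applies [percent_cross_reactivity()] and [categorize_cr()] row-wise.
#' Malformed rows (non-positive spike, negative readings, missing values) are
#' reported together by row number.
#'
#' @param measurements data.frame as from [read_measurements()].
#' @param provenance provenance string stamped on the records.
#' @return data.frame with columns `assay_name`, `compound_name`,
#'   `cross_reactivity_pct`, `category`, `provenance`.
#' @export
cross_reactivity_table <- function(measurements, provenance = "measured") {
  m <- measurements
  bad <- which(!is.finite(m$spike_ng_ml) | m$spike_ng_ml <= 0 |
                 !is.finite(m$apparent_spiked_ng_ml) | m$apparent_spiked_ng_ml < 0 |
                 !is.finite(m$apparent_baseline_ng_ml) | m$apparent_baseline_ng_ml < 0)
  if (length(bad)) stop("malformed measurement rows: ", paste(bad, collapse = ", "))
  cr <- percent_cross_reactivity(m$spike_ng_ml, m$apparent_spiked_ng_ml,
                                 m$apparent_baseline_ng_ml)
  data.frame(assay_name = m$assay, compound_name = m$compound,
             cross_reactivity_pct = cr, category = categorize_cr(cr),
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Count compounds per cross-reactivity category
#'
#' @param records data.frame of cross-reactivity records (one assay).
#' @param exclude_target drop the assay's own target analyte (cross-reactivity
#'   100 percent by definition) before counting.
#' @param target_name name of the target compound; when `NULL` it is looked up
#'   from the packaged assay definitions via `assay_name`.
#' @return named integer vector over [cr_categories].
#' @export
classify_panel <- function(records, exclude_target = TRUE, target_name = NULL) {
  counts <- stats::setNames(integer(length(cr_categories)), cr_categories)
  if (nrow(records) == 0L) return(counts)
  assays <- unique(records$assay_name)
  if (length(assays) != 1L)
    stop("records mix assays: ", paste(assays, collapse = ", "))
  if (exclude_target) {
    if (is.null(target_name)) {
      defs <- assay_definitions()
      hit <- defs$target_compound[defs$assay == assays]
      if (length(hit) == 0L)
        stop("unknown assay '", assays, "'; supply target_name")
      target_name <- hit
    }
    records <- records[records$compound_name != target_name, , drop = FALSE]
  }
  tab <- table(factor(as.character(records$category), levels = cr_categories))
  counts[names(tab)] <- as.integer(tab)
  counts
}
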