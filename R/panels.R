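#' Packaged assay panels
#'
#' Five electrochemiluminescence steroid immunoassay panels are packaged as
#' plain-text fixtures: transcribed cross-reactivity tables, plasma
#' concentration ranges from the pharmacokinetic literature, assay definitions
#' (target hapten, spike concentration, reference intervals, clinical decision
#' level) and curated structures for every panel compound.
#'
#' @return `available_assays()`: character vector of packaged assay names.
#' @export
available_assays <- function() {
  c("cortisol", "dhea_sulfate", "estradiol", "progesterone", "testosterone")
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "crossreact")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

fixture_csv <- function(file) {
  key <- paste0("csv_", file)
  if (is.null(.cr_cache[[key]]))
    .cr_cache[[key]] <- utils::read.csv(fixture_path(file), stringsAsFactors = FALSE)
  .cr_cache[[key]]
}

assay_definitions <- function() fixture_csv("assay_definitions.csv")

#' Assay definition
#'
#' @param assay_name one of [available_assays()].
#' @return list of class `xr_assay`: `assay_name`, `target_compound` (name),
#'   `spike_concentration` (ng/mL), `reference_intervals` (data.frame with
#'   `population`, `low_ng_ml`, `high_ng_ml`), `decision_level` (ng/mL; see
#'   [grade_likelihood()]).
#' @export
assay_definition <- function(assay_name) {
  defs <- assay_definitions()
  row <- defs[defs$assay == assay_name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown assay '", assay_name, "'; available: ",
         paste(available_assays(), collapse = ", "))
  ivs <- fixture_csv("reference_intervals.csv")
  ivs <- ivs[ivs$assay == assay_name, c("population", "low_ng_ml", "high_ng_ml")]
  rownames(ivs) <- NULL
  stopifnot(all(is.na(ivs$low_ng_ml) | is.na(ivs$high_ng_ml) |
                  ivs$low_ng_ml <= ivs$high_ng_ml))
  structure(list(assay_name = assay_name,
                 target_compound = row$target_compound,
                 spike_concentration = row$spike_ng_ml,
                 reference_intervals = ivs,
                 decision_level = row$decision_level_ng_ml),
            class = "xr_assay")
}

#' Load a packaged assay panel
#'
#' Returns the transcribed fixture for one assay: the assay definition, the
#' cross-reactivity records (with categories derived from the fixture CR
#' values, and the printed likelihood wording carried as
#' `likelihood_printed`), and the plasma concentration ranges.
#'
#' @param assay_name one of [available_assays()].
#' @return list with elements `assay` ([assay_definition()]), `records`
#'   (data.frame of cross-reactivity records) and `ranges` (data.frame of
#'   plasma ranges).
#' @export
#' @examples
#' panel <- load_fixture_panel("testosterone")
#' classify_panel(panel$records)
load_fixture_panel <- function(assay_name) {
  assay <- assay_definition(assay_name)
  cr <- fixture_csv("cross_reactivity.csv")
  cr <- cr[cr$assay == assay_name, , drop = FALSE]
  records <- data.frame(assay_name = cr$assay, compound_name = cr$compound,
                        cross_reactivity_pct = cr$cross_reactivity_pct,
                        category = categorize_cr(cr$cross_reactivity_pct),
                        provenance = cr$provenance,
                        likelihood_printed = cr$likelihood_printed,
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  pr <- fixture_csv("plasma_ranges.csv")
  pr <- pr[pr$assay == assay_name, , drop = FALSE]
  ranges <- data.frame(compound_name = pr$compound, population = pr$population,
                       low_ng_ml = pr$low_ng_ml, high_ng_ml = pr$high_ng_ml,
                       citation = pr$citation, stringsAsFactors = FALSE)
  rownames(ranges) <- NULL
  stopifnot(all(is.na(ranges$low_ng_ml) | ranges$high_ng_ml >= ranges$low_ng_ml),
            all(ranges$high_ng_ml > 0))
  list(assay = assay, records = records, ranges = ranges)
}

#' Packaged compound structures
#'
#' Curated SMILES for every compound named in the packaged panels (plus the
#' additional compounds discussed alongside them, e.g. tetrahydrocortisone and
#' estropipate). Structures are curated from canonical structure references;
#' they are inputs to the pipeline, not outputs.
#'
#' @param standardized standardize the structures (default `TRUE`; see
#'   [standardize_compound()]).
#' @return named list of [compound()] objects.
#' @export
load_compound_library <- function(standardized = TRUE) {
  key <- if (standardized) "library_std" else "library_raw"
  if (is.null(.cr_cache[[key]])) {
    cps <- read_smiles_file(fixture_path("steroid_smiles.smi"))
    if (standardized) cps <- standardize_compounds(cps)
    names(cps) <- vapply(cps, `[[`, character(1), "name")
    .cr_cache[[key]] <- cps
  }
  .cr_cache[[key]]
}

#' @rdname load_compound_library
#' @param name compound name.
#' @export
get_compound <- function(name, standardized = TRUE) {
  lib <- load_compound_library(standardized)
  if (!name %in% names(lib))
    stop("compound '", name, "' is not in the packaged library")
  lib[[name]]
}
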