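#' Similarity of a structure file against an assay target
#'
#' Reads compounds (`.smi` or `.sdf` by extension), standardizes them, scores
#' each against the target and writes a CSV (`query_name`, `reference_name`,
#' `tanimoto`, 3 decimals). The target is taken from the input file when
#' present, else from the packaged compound library.
#'
#' @param structures path to a SMILES line file or SDF; `NULL` uses the
#'   packaged library.
#' @param target name of the target compound.
#' @param out output CSV path.
#' @param dict key dictionary (default packaged `v1`).
#' @return the score data.frame, invisibly.
#' @export
cmd_similarity <- function(structures, target, out, dict = NULL) {
  cps <- if (is.null(structures)) {
    load_compound_library(standardized = FALSE)
  } else if (grepl("\\.sdf$", structures, ignore.case = TRUE)) {
    read_sdf_file(structures)
  } else {
    read_smiles_file(structures)
  }
  nms <- vapply(cps, `[[`, character(1), "name")
  tgt <- if (target %in% nms) {
    cps[[which(nms == target)[1]]]
  } else if (target %in% names(load_compound_library(standardized = FALSE))) {
    get_compound(target, standardized = FALSE)
  } else {
    stop("target '", target, "' not found in input or packaged library")
  }
  cps <- standardize_compounds(cps)
  tgt <- standardize_compound(tgt)
  scores <- similarity_panel(list(tgt), cps, dict)
  scores$tanimoto <- round(scores$tanimoto, 3)
  utils::write.csv(scores, out, row.names = FALSE)
  invisible(scores)
}

#' Classify spiked-sample measurements
#'
#' Reads a measurement CSV, appends percent cross-reactivity and category,
#' writes the result, and logs per-category counts to stderr.
#'
#' @param measurements input CSV path (see [read_measurements()] for schema).
#' @param out output CSV path.
#' @return the classified data.frame, invisibly.
#' @export
cmd_classify <- function(measurements, out) {
  m <- read_measurements(measurements)
  rec <- cross_reactivity_table(m)
  res <- cbind(m, cross_reactivity_pct = rec$cross_reactivity_pct,
               category = as.character(rec$category))
  utils::write.csv(res, out, row.names = FALSE)
  tab <- table(factor(res$category, levels = cr_categories))
  message("category counts: ",
          paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "))
  invisible(res)
}

#' Full interference and triage report for a packaged assay
#'
#' Runs the end-to-end analysis for one assay: similarity of every panel
#' compound to the target, interference estimates with likelihood grades, the
#' category similarity statistics and a similarity cutoff sweep. Writes
#' `interference.csv`/`interference.json`, `similarity.csv`,
#' `category_stats.csv`, `threshold_sweep.csv` and a `manifest.json` with the
#' run configuration, dictionary version and MD5 checksums of every output.
#' Reruns with the same inputs are byte-identical.
#'
#' @param assay_name one of [available_assays()].
#' @param out_dir output directory (created if needed).
#' @param cutoffs similarity cutoffs for the sweep.
#' @param figures also render a similarity-by-category strip plot PNG.
#' @param thresholds see [likelihood_thresholds()].
#' @param dict key dictionary (default packaged `v1`).
#' @return list with the computed tables, invisibly.
#' @export
cmd_report <- function(assay_name, out_dir, cutoffs = seq(0, 1, by = 0.05),
                       figures = FALSE, thresholds = likelihood_thresholds(),
                       dict = NULL) {
  panel <- load_fixture_panel(assay_name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dict)) dict <- default_key_dictionary()

  lib <- load_compound_library()
  tgt <- lib[[panel$assay$target_compound]]
  cps <- lib[panel$records$compound_name]
  scores <- similarity_panel(list(tgt), cps, dict)
  scores$tanimoto <- round(scores$tanimoto, 3)

  interf <- interference_report(panel$assay, panel$records, panel$ranges,
                                thresholds = thresholds)
  stats <- category_similarity_stats(scores, panel$records)
  sweep <- threshold_sweep(scores, panel$records, cutoffs)

  paths <- c(similarity = "similarity.csv", interference = "interference.csv",
             category_stats = "category_stats.csv",
             threshold_sweep = "threshold_sweep.csv")
  paths <- vapply(paths, function(f) file.path(out_dir, f), character(1))
  utils::write.csv(scores, paths[["similarity"]], row.names = FALSE)
  write_interference_report(interf, csv_path = paths[["interference"]],
                            json_path = file.path(out_dir, "interference.json"))
  utils::write.csv(stats, paths[["category_stats"]], row.names = FALSE)
  utils::write.csv(sweep, paths[["threshold_sweep"]], row.names = FALSE)
  outputs <- c(paths, interference_json = file.path(out_dir, "interference.json"))

  if (figures) {
    png_path <- file.path(out_dir, "similarity_by_category.png")
    grDevices::png(png_path, width = 800, height = 600)
    plot_similarity_by_category(scores, panel$records, main = assay_name)
    grDevices::dev.off()
    outputs <- c(outputs, figure = png_path)
  }

  manifest <- list(
    assay = assay_name,
    dictionary_version = dictionary_version(dict),
    spike_concentration_ng_ml = panel$assay$spike_concentration,
    likelihood_thresholds = thresholds,
    cutoffs = cutoffs,
    outputs = as.list(stats::setNames(unname(tools::md5sum(unname(outputs))),
                                      basename(unname(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scores = scores, interference = interf,
                 category_stats = stats, sweep = sweep, manifest = manifest))
}
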