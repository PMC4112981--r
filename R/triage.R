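#' Similarity statistics per cross-reactivity category
#'
#' Joins similarity scores to cross-reactivity records on compound name and
#' summarises similarity within each category (the per-column averages of the
#' similarity-versus-category strip plots). The assay target itself
#' (query equal to reference) is excluded.
#'
#' @param scores data.frame from [similarity_panel()] (single reference).
#' @param records cross-reactivity records for the same panel.
#' @return data.frame with one row per category: `category`, `n`,
#'   `mean_similarity`, `min_similarity`, `max_similarity`.
#' @export
category_similarity_stats <- function(scores, records) {
  refs <- unique(scores$reference_name)
  scores <- scores[scores$query_name != scores$reference_name, , drop = FALSE]
  records <- records[!(records$compound_name %in% refs), , drop = FALSE]
  missing <- setdiff(records$compound_name, scores$query_name)
  if (length(missing))
    stop("no similarity score for: ", paste(missing, collapse = ", "))
  joined <- merge(records, scores, by.x = "compound_name", by.y = "query_name")
  out <- do.call(rbind, lapply(cr_categories, function(cat) {
    s <- joined$tanimoto[as.character(joined$category) == cat]
    data.frame(category = cat, n = length(s),
               mean_similarity = if (length(s)) mean(s) else NA_real_,
               min_similarity = if (length(s)) min(s) else NA_real_,
               max_similarity = if (length(s)) max(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$category <- factor(out$category, levels = cr_categories, ordered = TRUE)
  out
}

# join scores to records and derive the triage truth labels
triage_join <- function(scores, records, very_weak) {
  scores <- scores[scores$query_name != scores$reference_name, , drop = FALSE]
  joined <- merge(records, scores, by.x = "compound_name", by.y = "query_name")
  cat <- as.character(joined$category)
  joined$truth <- ifelse(cat %in% c("strong", "weak"), "positive",
                         ifelse(cat == "none", "negative",
                                switch(very_weak, exclude = NA_character_,
                                       positive = "positive",
                                       negative = "negative")))
  joined
}

#' Sweep similarity cutoffs as a cross-reactivity triage classifier
#'
#' At each cutoff, compounds with similarity at or above the cutoff are
#' flagged. Positives are the strong and weak cross-reactive compounds,
#' negatives the non-cross-reactive ones; the ambiguous very-weak category is
#' excluded by default (`very_weak = "exclude"`) but can be counted on either
#' side. Sensitivity is the flagged fraction of positives, specificity the
#' unflagged fraction of negatives.
#'
#' @inheritParams category_similarity_stats
#' @param cutoffs similarity cutoffs in `[0, 1]`.
#' @param very_weak `"exclude"`, `"positive"` or `"negative"`.
#' @return data.frame with one row per cutoff: confusion counts (`tp`, `fn`,
#'   `tn`, `fp`), `sensitivity`, `specificity`, and per-category counts at or
#'   above (`<category>_ge`) and below (`<category>_lt`) the cutoff.
#' @export
threshold_sweep <- function(scores, records, cutoffs = seq(0, 1, by = 0.05),
                            very_weak = c("exclude", "positive", "negative")) {
  very_weak <- match.arg(very_weak)
  stopifnot(all(cutoffs >= 0 & cutoffs <= 1))
  joined <- triage_join(scores, records, very_weak)
  out <- do.call(rbind, lapply(cutoffs, function(ct) {
    ge <- joined$tanimoto >= ct
    tp <- sum(ge & joined$truth == "positive", na.rm = TRUE)
    fn <- sum(!ge & joined$truth == "positive", na.rm = TRUE)
    fp <- sum(ge & joined$truth == "negative", na.rm = TRUE)
    tn <- sum(!ge & joined$truth == "negative", na.rm = TRUE)
    row <- data.frame(cutoff = ct, tp = tp, fn = fn, tn = tn, fp = fp,
                      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
    for (cat in cr_categories) {
      inc <- as.character(joined$category) == cat
      row[[paste0(cat, "_ge")]] <- sum(inc & ge)
      row[[paste0(cat, "_lt")]] <- sum(inc & !ge)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Flag candidate compounds at or above a similarity cutoff
#'
#' Matches the "similarity of X or higher" reading: compounds exactly at the
#' cutoff are flagged. Sorted by descending similarity, ties alphabetical.
#'
#' @param scores data.frame from [similarity_panel()].
#' @param cutoff similarity cutoff in `[0, 1]`.
#' @return character vector of compound names.
#' @export
flag_candidates <- function(scores, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  hit <- scores[scores$tanimoto >= cutoff, , drop = FALSE]
  hit <- hit[order(-hit$tanimoto, hit$query_name), , drop = FALSE]
  hit$query_name
}

#' Strip plot of similarity by cross-reactivity category
#'
#' Mirrors the similarity-versus-category panels of the assay figures: one
#' jittered column per category with a horizontal bar at the category mean.
#'
#' @inheritParams category_similarity_stats
#' @param main plot title.
#' @return the joined plotting data, invisibly.
#' @export
plot_similarity_by_category <- function(scores, records, main = "") {
  joined <- triage_join(scores, records, very_weak = "exclude")
  xi <- match(as.character(joined$category), cr_categories)
  set.seed(1)  # cosmetic jitter only
  graphics::plot(xi + stats::runif(length(xi), -0.15, 0.15), joined$tanimoto,
                 xlim = c(0.5, 4.5), ylim = c(0, 1), xaxt = "n",
                 xlab = "cross-reactivity category", ylab = "Tanimoto similarity",
                 pch = 19, col = "grey30", main = main)
  graphics::axis(1, at = seq_along(cr_categories), labels = cr_categories)
  for (k in seq_along(cr_categories)) {
    s <- joined$tanimoto[as.character(joined$category) == cr_categories[k]]
    if (length(s))
      graphics::segments(k - 0.25, mean(s), k + 0.25, mean(s), lwd = 2, col = "red")
  }
  invisible(joined)
}
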