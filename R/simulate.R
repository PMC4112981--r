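#' Configuration for a synthetic assay panel
#'
#' The simulator draws a panel of compounds with 2D similarities uniform on
#' `[0, 1]` and gives each a true percent cross-reactivity through a noisy
#' logistic link, then produces spiked-sample readouts with multiplicative
#' assay imprecision:
#' \deqn{E[CR](s) = link\_max / (1 + e^{-link\_slope (s - link\_midpoint)})}
#' \deqn{CR_{true} = E[CR](s) \cdot e^{\epsilon},\ \epsilon \sim N(0, noise\_sd\_log^2)}
#' \deqn{A_{spiked} = (baseline + CR_{true}/100 \cdot spike)(1 + \delta),\ \delta \sim N(0, cv^2)}
#' The defaults encode the threshold-like relation seen across steroid assay
#' panels: the strong-cross-reactivity onset (5 percent) sits near similarity 0.73
#' and the weak onset (0.5 percent) near 0.67 (see the methods vignette).
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_compounds panel size.
#' @param spike_concentration ng/mL of test compound added (default 1000, the
#'   typical challenge concentration).
#' @param assay_cv fractional coefficient of variation of the readout
#'   (default 0.05, typical automated immunoassay imprecision).
#' @param baseline_level apparent analyte in the unspiked matrix, ng/mL
#'   (default 5: a low-analyte plasma pool, as interference protocols
#'   prescribe).
#' @param link_midpoint similarity at which expected CR is half of `link_max`.
#' @param link_slope logistic steepness (> 0).
#' @param link_max asymptotic expected CR, percent.
#' @param noise_sd_log SD of the lognormal scatter of true CR about the link.
#' @return list of class `xr_sim_config`.
#' @export
simulation_config <- function(seed, n_compounds = 100, spike_concentration = 1000,
                              assay_cv = 0.05, baseline_level = 5,
                              link_midpoint = 0.8, link_slope = 40,
                              link_max = 100, noise_sd_log = 0.2) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              spike_concentration = spike_concentration, assay_cv = assay_cv,
              baseline_level = baseline_level, link_midpoint = link_midpoint,
              link_slope = link_slope, link_max = link_max,
              noise_sd_log = noise_sd_log)
  with(cfg, {
    if (n_compounds < 1) stop("n_compounds must be >= 1")
    if (spike_concentration <= 0) stop("spike_concentration must be > 0")
    if (assay_cv < 0 || noise_sd_log < 0) stop("noise parameters must be >= 0")
    if (baseline_level < 0) stop("baseline_level must be >= 0")
    if (link_slope <= 0 || link_max <= 0) stop("link parameters must be > 0")
    if (link_midpoint < 0 || link_midpoint > 1) stop("link_midpoint must be in [0,1]")
  })
  structure(cfg, class = "xr_sim_config")
}

cr_link <- function(s, cfg) {
  cfg$link_max / (1 + exp(-cfg$link_slope * (s - cfg$link_midpoint)))
}

# one readout of the panel under the config's noise model
draw_measurements <- function(panel_df, cfg) {
  n <- nrow(panel_df)
  noise <- function() 1 + stats::rnorm(n, 0, cfg$assay_cv)
  signal <- cfg$baseline_level + panel_df$true_cr / 100 * cfg$spike_concentration
  data.frame(assay = "simulated", compound = panel_df$compound,
             spike_ng_ml = cfg$spike_concentration,
             apparent_spiked_ng_ml = pmax(0, signal * noise()),
             apparent_baseline_ng_ml = pmax(0, cfg$baseline_level * noise()),
             stringsAsFactors = FALSE)
}

simulate_panel_core <- function(cfg) {
  s <- stats::runif(cfg$n_compounds)
  expected <- cr_link(s, cfg)
  true_cr <- expected * stats::rlnorm(cfg$n_compounds, 0, cfg$noise_sd_log)
  df <- data.frame(compound = sprintf("compound_%04d", seq_len(cfg$n_compounds)),
                   similarity = s, expected_cr = expected, true_cr = true_cr,
                   true_category = categorize_cr(true_cr),
                   stringsAsFactors = FALSE)
  list(config = cfg, compounds = df, measurements = draw_measurements(df, cfg))
}

#' Simulate a synthetic assay panel
#'
#' @param config from [simulation_config()].
#' @return list of class `xr_sim_panel`: `config`, `compounds` (per-compound
#'   similarity, expected and true CR, true category) and `measurements`
#'   (spiked-sample readouts in the measurement CSV schema, directly
#'   consumable by [cross_reactivity_table()] / [cmd_classify()]).
#' @export
#' @examples
#' p <- simulate_panel(simulation_config(seed = 1, n_compounds = 10))
#' head(p$measurements)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "xr_sim_config"))
  set.seed(config$seed)
  structure(simulate_panel_core(config), class = "xr_sim_panel")
}

#' Replicate-measurement recovery experiment
#'
#' Simulates one panel, then `n_replicates` independent readouts of it, and
#' summarises how well percent cross-reactivity and its category are recovered
#' from the noisy measurements.
#'
#' @inheritParams simulate_panel
#' @param n_replicates number of replicate readouts (>= 1).
#' @param edge_factor multiplicative distance from a bin edge below which a
#'   compound is considered edge-adjacent (see [cr_edge_safe()]).
#' @return list with `per_compound` (true CR, mean/SD of the estimates, bias,
#'   recovered category, `edge_safe`) and `summary` (mean relative bias over
#'   compounds with true CR >= 0.5 percent, overall and edge-safe category
#'   agreement).
#' @export
recovery_experiment <- function(config, n_replicates, edge_factor = 2) {
  stopifnot(inherits(config, "xr_sim_config"), n_replicates >= 1)
  set.seed(config$seed)
  panel <- simulate_panel_core(config)
  est <- replicate(n_replicates, {
    m <- draw_measurements(panel$compounds, config)
    suppressMessages(percent_cross_reactivity(
      m$spike_ng_ml, m$apparent_spiked_ng_ml, m$apparent_baseline_ng_ml))
  })
  est <- matrix(est, nrow = config$n_compounds)
  mean_est <- rowMeans(est)
  sd_est <- if (n_replicates > 1) apply(est, 1, stats::sd) else rep(NA_real_, nrow(est))
  per <- data.frame(compound = panel$compounds$compound,
                    similarity = panel$compounds$similarity,
                    true_cr = panel$compounds$true_cr,
                    mean_cr = mean_est, sd_cr = sd_est,
                    bias = mean_est - panel$compounds$true_cr,
                    true_category = panel$compounds$true_category,
                    est_category = categorize_cr(mean_est),
                    edge_safe = cr_edge_safe(panel$compounds$true_cr, edge_factor),
                    stringsAsFactors = FALSE)
  quant <- per$true_cr >= 0.5
  summary <- list(
    n_compounds = nrow(per), n_replicates = n_replicates,
    mean_relative_bias = mean(per$bias[quant] / per$true_cr[quant]),
    category_agreement = mean(per$est_category == per$true_category),
    category_agreement_edge_safe =
      mean((per$est_category == per$true_category)[per$edge_safe]))
  list(per_compound = per, summary = summary)
}

#' Is a cross-reactivity value safely away from the category bin edges?
#'
#' Categories are bounded at 0.05, 0.5 and 5 percent; a value is edge-safe
#' when its multiplicative distance to every edge is at least `factor` (i.e.
#' it lies outside `[edge/factor, edge*factor]` for each edge).
#'
#' @param cr percent cross-reactivity (vectorized).
#' @param factor multiplicative safety factor (default 2).
#' @return logical vector.
#' @export
cr_edge_safe <- function(cr, factor = 2) {
  stopifnot(factor >= 1)
  ok <- rep(TRUE, length(cr))
  for (edge in cr_bin_edges) ok <- ok & (cr <= edge / factor | cr >= edge * factor)
  ok
}

#' Export simulated measurements in the measurement CSV schema
#'
#' @param panel from [simulate_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_measurements <- function(panel, path) {
  stopifnot(inherits(panel, "xr_sim_panel"))
  utils::write.csv(panel$measurements, path, row.names = FALSE)
  invisible(path)
}
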