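#' The four molecular subtype labels
#'
#' Canonical ordering of the head and neck squamous cell carcinoma (HNSCC)
#' expression subtypes used throughout the package. The order is also the
#' tie-break order when a sample is exactly equidistant from two centroids.
#'
#' @export
hnscc_subtypes <- c("basal", "mesenchymal", "classical", "atypical")

#' Anatomic sites
#' @export
hnscc_sites <- c("oral_cavity", "larynx", "oropharynx", "hypopharynx")

#' HPV types used for status calling
#' @export
hpv_types <- c("HPV16", "HPV18", "HPV33", "HPV35")

#' Configuration for the synthetic-cohort generator
#'
#' Builds a validated configuration list for [simulate_cohort()] and its
#' component stages. The defaults describe an HNSCC-like cohort: 418 samples,
#' subtype mix 30% basal / 26% mesenchymal / 18% classical / 26% atypical,
#' nodal positivity 0.67 for mesenchymal versus 0.55 otherwise, anatomic-site
#' frequencies dominated by the oral cavity, a ~15% HPV-positive rate, and an
#' exponential survival model in which node-negative mesenchymal disease and
#' any node-positive disease both carry a hazard ratio of 2.4 against
#' node-negative non-mesenchymal disease, with administrative censoring at 36
#' months. All distributional forms (Gaussian log2 expression, exponential
#' event times, uniform viral counts) are synthetic stand-ins chosen for
#' testability, not estimates from real data.
#'
#' @param n_samples Number of samples to simulate.
#' @param subtype_proportions Named probabilities over [hnscc_subtypes];
#'   must sum to 1.
#' @param n_marker_genes_per_subtype Marker genes per subtype (half shifted
#'   up, half down in that subtype); must be an even number >= 2.
#' @param n_noise_genes Genes carrying no subtype signal.
#' @param marker_effect_size Standardised mean shift of marker genes, in
#'   units of `noise_sd` (log2 scale).
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param node_positive_prob_by_subtype Named probability of node-positive
#'   (N+) disease per subtype.
#' @param site_probs Named probabilities over [hnscc_sites].
#' @param hazard_rate_baseline Baseline event hazard, events per month, for
#'   node-negative non-mesenchymal disease.
#' @param hazard_ratio_mesenchymal_n0 Hazard ratio for node-negative
#'   mesenchymal versus baseline.
#' @param hazard_ratio_node_positive Hazard ratio for node-positive disease
#'   (any subtype) versus baseline.
#' @param censor_horizon Administrative censoring horizon, months.
#' @param hpv_positive_prob Probability a sample is truly HPV-positive.
#' @param hpv_positive_count_range Integer range (inclusive) for the read
#'   count of the infecting type in HPV-positive samples.
#' @param hpv_negative_count_range Integer range for all counts in
#'   HPV-negative samples (and non-infecting types in positive samples).
#'   Must lie entirely below `hpv_positive_count_range`.
#' @param seed Integer seed governing every random draw of the generator.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_samples = 100, seed = 1)
#' cfg$subtype_proportions
#' @export
sim_config <- function(n_samples = 418,
                       subtype_proportions = c(basal = 0.30, mesenchymal = 0.26,
                                               classical = 0.18, atypical = 0.26),
                       n_marker_genes_per_subtype = 40,
                       n_noise_genes = 500,
                       marker_effect_size = 4,
                       noise_sd = 1,
                       node_positive_prob_by_subtype = c(basal = 0.55, mesenchymal = 0.67,
                                                         classical = 0.55, atypical = 0.55),
                       site_probs = c(oral_cavity = 269 / 418, larynx = 95 / 418,
                                      oropharynx = 47 / 418, hypopharynx = 7 / 418),
                       hazard_rate_baseline = 0.01,
                       hazard_ratio_mesenchymal_n0 = 2.4,
                       hazard_ratio_node_positive = 2.4,
                       censor_horizon = 36,
                       hpv_positive_prob = 63 / 418,
                       hpv_positive_count_range = c(5000L, 50000L),
                       hpv_negative_count_range = c(0L, 100L),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    subtype_proportions = subtype_proportions,
    n_marker_genes_per_subtype = as.integer(n_marker_genes_per_subtype),
    n_noise_genes = as.integer(n_noise_genes),
    marker_effect_size = marker_effect_size,
    noise_sd = noise_sd,
    node_positive_prob_by_subtype = node_positive_prob_by_subtype,
    site_probs = site_probs,
    hazard_rate_baseline = hazard_rate_baseline,
    hazard_ratio_mesenchymal_n0 = hazard_ratio_mesenchymal_n0,
    hazard_ratio_node_positive = hazard_ratio_node_positive,
    censor_horizon = censor_horizon,
    hpv_positive_prob = hpv_positive_prob,
    hpv_positive_count_range = as.integer(hpv_positive_count_range),
    hpv_negative_count_range = as.integer(hpv_negative_count_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples <= 0) abort("`n_samples` must be strictly positive.")
  p <- cfg$subtype_proportions
  if (!setequal(names(p), hnscc_subtypes)) {
    abort("`subtype_proportions` must be named with the four subtypes.")
  }
  if (abs(sum(p) - 1) > 1e-9) abort("`subtype_proportions` must sum to 1.")
  probs <- c(p, cfg$node_positive_prob_by_subtype, cfg$site_probs,
             cfg$hpv_positive_prob)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (!setequal(names(cfg$node_positive_prob_by_subtype), hnscc_subtypes)) {
    abort("`node_positive_prob_by_subtype` must be named with the four subtypes.")
  }
  if (!setequal(names(cfg$site_probs), hnscc_sites)) {
    abort("`site_probs` must be named with the four anatomic sites.")
  }
  if (abs(sum(cfg$site_probs) - 1) > 1e-9) abort("`site_probs` must sum to 1.")
  if (cfg$n_marker_genes_per_subtype < 2 || cfg$n_marker_genes_per_subtype %% 2 != 0) {
    abort("`n_marker_genes_per_subtype` must be an even number >= 2.")
  }
  if (cfg$n_noise_genes < 0) abort("`n_noise_genes` must be non-negative.")
  if (cfg$marker_effect_size < 0) abort("`marker_effect_size` must be >= 0.")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be strictly positive.")
  if (cfg$hazard_rate_baseline <= 0) abort("`hazard_rate_baseline` must be strictly positive.")
  if (cfg$hazard_ratio_mesenchymal_n0 <= 0 || cfg$hazard_ratio_node_positive <= 0) {
    abort("Hazard ratios must be strictly positive.")
  }
  if (cfg$censor_horizon <= 0) abort("`censor_horizon` must be strictly positive.")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && all(r >= 0)
  if (!rng_ok(cfg$hpv_positive_count_range) || !rng_ok(cfg$hpv_negative_count_range)) {
    abort("HPV count ranges must be non-negative intervals c(lo, hi).")
  }
  if (cfg$hpv_negative_count_range[2] >= cfg$hpv_positive_count_range[1]) {
    abort("`hpv_positive_count_range` must lie entirely above `hpv_negative_count_range`.")
  }
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML keys mirror the [sim_config()] argument names exactly, so a config
#' file round-trips losslessly.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("subtype_proportions", "node_positive_prob_by_subtype", "site_probs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("hpv_positive_count_range", "hpv_negative_count_range")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.integer(unlist(raw[[nm]]))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  out <- unclass(config)
  out$subtype_proportions <- as.list(out$subtype_proportions)
  out$node_positive_prob_by_subtype <- as.list(out$node_positive_prob_by_subtype)
  out$site_probs <- as.list(out$site_probs)
  yaml::write_yaml(out, path)
  invisible(path)
}
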