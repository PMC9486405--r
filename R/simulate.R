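# Synthetic-cohort generator. All draws flow from config$seed; each stage
# uses a fixed offset of that seed so stages are reproducible in isolation
# and statistically independent of each other.
.seed_offset <- c(expression = 11L, clinical = 12L, survival = 13L, hpv = 14L)

#' Simulate a log2 expression matrix with subtype marker structure
#'
#' Generates a gene-by-sample matrix on the log2 scale. Each subtype owns a
#' disjoint block of marker genes, half shifted up and half shifted down by
#' `marker_effect_size * noise_sd` in that subtype's samples; all remaining
#' genes are pure noise. Every gene gets its own baseline level drawn once
#' from U(4, 12) log2 units, with Gaussian noise of sd `noise_sd` on top.
#' This is a deliberately simple stand-in for bulk RNA-seq structure: no
#' count-level dispersion, batch effects or tumor purity are modelled.
#'
#' @param config A [sim_config()] object.
#' @return A list with `expression` (tibble: `gene` column then one column
#'   per sample, log2 scale) and `labels` (tibble: `sample_id`, `subtype`).
#' @examples
#' sim <- simulate_expression(sim_config(n_samples = 20, seed = 7))
#' dim(sim$expression)
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + .seed_offset[["expression"]], {
    n <- config$n_samples
    m <- config$n_marker_genes_per_subtype
    sample_ids <- sprintf("S%04d", seq_len(n))
    subtype <- sample(hnscc_subtypes, n, replace = TRUE,
                      prob = config$subtype_proportions[hnscc_subtypes])

    marker_genes <- unlist(lapply(hnscc_subtypes, function(st) {
      sprintf("MK_%s_%s_%03d", st, rep(c("up", "dn"), each = m / 2),
              c(seq_len(m / 2), seq_len(m / 2)))
    }))
    noise_genes <- sprintf("NG_%04d", seq_len(config$n_noise_genes))
    genes <- c(marker_genes, noise_genes)

    baseline <- runif(length(genes), 4, 12)
    values <- matrix(rnorm(length(genes) * n, mean = 0, sd = config$noise_sd),
                     nrow = length(genes)) + baseline
    rownames(values) <- genes
    colnames(values) <- sample_ids

    shift <- config$marker_effect_size * config$noise_sd
    for (st in hnscc_subtypes) {
      in_st <- subtype == st
      if (!any(in_st)) next
      up <- grep(sprintf("^MK_%s_up_", st), genes)
      dn <- grep(sprintf("^MK_%s_dn_", st), genes)
      values[up, in_st] <- values[up, in_st] + shift
      values[dn, in_st] <- values[dn, in_st] - shift
    }

    list(
      expression = expression_tibble(values),
      labels = tibble(sample_id = sample_ids, subtype = subtype)
    )
  })
}

#' Simulate clinical covariates for labelled samples
#'
#' Draws nodal status from the per-subtype positivity probabilities in the
#' configuration, and anatomic site, T stage, age, gender, smoking, radiation
#' and true HPV status from fixed marginals typical of an HNSCC cohort
#' (radiation probability depends on nodal status). Overall stage is derived
#' from T and N stage by the usual grouping (N+ implies stage III/IV).
#'
#' @param labels Tibble with `sample_id` and `subtype` columns (from
#'   [simulate_expression()]).
#' @param config A [sim_config()] object.
#' @return A cohort tibble: one row per sample with site, T/N/overall stage,
#'   `node_binary`, age, gender, smoker, hpv, radiation, subtype and
#'   `mesenchymal_binary` columns.
#' @export
simulate_clinical <- function(labels, config) {
  validate_sim_config(config)
  if (nrow(labels) == 0) abort("`labels` must contain at least one sample.")
  unknown <- setdiff(unique(labels$subtype), hnscc_subtypes)
  if (length(unknown) > 0) {
    abort(paste0("Unknown subtype label(s): ", paste(unknown, collapse = ", ")))
  }
  withr::with_seed(config$seed + .seed_offset[["clinical"]], {
    n <- nrow(labels)
    p_node <- config$node_positive_prob_by_subtype[labels$subtype]
    node_pos <- rbinom(n, 1, p_node) == 1
    n_stage <- ifelse(node_pos,
                      sample(c("N1", "N2", "N3"), n, replace = TRUE,
                             prob = c(0.28, 0.69, 0.03)),
                      "N0")
    t_stage <- sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                      prob = c(0.10, 0.27, 0.23, 0.40))
    cohort <- labels |>
      mutate(
        site = sample(hnscc_sites, n, replace = TRUE,
                      prob = config$site_probs[hnscc_sites]),
        T_stage = t_stage,
        N_stage = n_stage,
        age = pmin(pmax(round(rnorm(n, mean = 61, sd = 11)), 19), 90),
        gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.74, 0.26)),
        smoker = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.78, 0.22)),
        hpv = ifelse(rbinom(n, 1, config$hpv_positive_prob) == 1,
                     "positive", "negative"),
        radiation = ifelse(rbinom(n, 1, ifelse(node_pos, 0.75, 0.45)) == 1,
                           "yes", "no")
      ) |>
      derive_cohort_columns()
    cohort[, c("sample_id", "site", "site_group", "T_stage", "N_stage",
               "node_binary", "overall_stage", "age", "gender", "smoker",
               "hpv", "radiation", "subtype", "mesenchymal_binary")]
  })
}

#' Simulate survival outcomes under a subtype-by-node hazard model
#'
#' Event times are exponential with hazard `hazard_rate_baseline` multiplied
#' by `hazard_ratio_node_positive` for node-positive samples and by
#' `hazard_ratio_mesenchymal_n0` for node-negative mesenchymal samples
#' (node-negative non-mesenchymal is the reference). Administrative censoring
#' is applied at `censor_horizon` months; an event at exactly the horizon is
#' kept as an event.
#'
#' @param cohort Cohort tibble with `subtype` and `node_binary` columns.
#' @param config A [sim_config()] object.
#' @return The cohort with `time` (months) and `event` (0/1) columns added.
#' @export
simulate_survival <- function(cohort, config) {
  validate_sim_config(config)
  if (!all(c("subtype", "node_binary") %in% names(cohort))) {
    abort("`cohort` must have `subtype` and `node_binary` columns.")
  }
  withr::with_seed(config$seed + .seed_offset[["survival"]], {
    hr <- ifelse(cohort$node_binary == "N+", config$hazard_ratio_node_positive,
                 ifelse(cohort$subtype == "mesenchymal",
                        config$hazard_ratio_mesenchymal_n0, 1))
    hazard <- config$hazard_rate_baseline * hr
    if (any(hazard <= 0)) abort("All hazards must be strictly positive.")
    raw_time <- rexp(nrow(cohort), rate = hazard)
    cens <- censor_at_horizon(raw_time, rep(1L, nrow(cohort)),
                              config$censor_horizon)
    cohort |> mutate(time = cens$time, event = cens$event)
  })
}

#' Simulate per-sample HPV read counts for types 16, 18, 33 and 35
#'
#' HPV-positive samples receive one infecting type chosen uniformly, with a
#' read count drawn uniformly from `hpv_positive_count_range`; every other
#' count (all counts for negative samples) is drawn from
#' `hpv_negative_count_range`. The default ranges straddle the 1,000-count
#' calling threshold so true status is recoverable exactly.
#'
#' @param labels Tibble with `sample_id` and `hpv` (`"positive"`/`"negative"`)
#'   columns.
#' @param config A [sim_config()] object.
#' @return Tibble with `sample_id` and integer columns `HPV16`, `HPV18`,
#'   `HPV33`, `HPV35`.
#' @export
simulate_hpv_counts <- function(labels, config) {
  validate_sim_config(config)
  if (!all(c("sample_id", "hpv") %in% names(labels))) {
    abort("`labels` must have `sample_id` and `hpv` columns.")
  }
  withr::with_seed(config$seed + .seed_offset[["hpv"]], {
    n <- nrow(labels)
    draw <- function(range, k) {
      sample(seq(range[1], range[2]), k, replace = TRUE)
    }
    counts <- matrix(draw(config$hpv_negative_count_range, n * 4L), nrow = n)
    colnames(counts) <- hpv_types
    pos <- which(labels$hpv == "positive")
    if (length(pos) > 0) {
      infecting <- sample(seq_along(hpv_types), length(pos), replace = TRUE)
      counts[cbind(pos, infecting)] <- draw(config$hpv_positive_count_range,
                                            length(pos))
    }
    dplyr::bind_cols(tibble(sample_id = labels$sample_id), as_tibble(counts))
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generator stages — expression, clinical covariates, survival
#' outcomes and HPV counts — under a single seed and returns them together
#' with the ground-truth label table used for recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expression` (gene x sample tibble),
#'   `cohort` (clinical + survival tibble), `hpv_counts`, and `truth`
#'   (tibble: `sample_id`, `subtype`, `node_binary`, `hpv`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 50, seed = 3))
#' names(sim)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  expr <- simulate_expression(config)
  cohort <- simulate_clinical(expr$labels, config)
  cohort <- simulate_survival(cohort, config)
  hpv_counts <- simulate_hpv_counts(cohort, config)
  truth <- cohort |> select("sample_id", "subtype", "node_binary", "hpv")
  list(expression = expr$expression, cohort = cohort,
       hpv_counts = hpv_counts, truth = truth)
}
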