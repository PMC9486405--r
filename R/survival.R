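# Horizon-censored survival analysis: Kaplan-Meier, log-rank, Cox.
# The heavy lifting is delegated to the survival package; this module owns
# the horizon-censoring rule, the cohort-specific stratification layout and
# tidy reporting.

#' Configuration for survival analysis
#'
#' @param horizon Administrative censoring horizon in months (default 36):
#'   follow-up longer than the horizon is truncated and censored there.
#' @param tie_method Partial-likelihood tie handling, `"efron"` (default)
#'   or `"breslow"` (for comparison with older software).
#' @param ci_level Confidence level for hazard-ratio intervals
#'   (default 0.95).
#' @param min_stratum Minimum stratum size below which results are flagged
#'   (not suppressed; default 10).
#' @param reference_levels Named list mapping covariate to its reference
#'   category for Cox fits.
#' @return List of class `"survival_config"`.
#' @export
survival_config <- function(horizon = 36, tie_method = c("efron", "breslow"),
                            ci_level = 0.95, min_stratum = 10,
                            reference_levels = list(
                              gender = "F", smoker = "no", hpv = "positive",
                              radiation = "yes", t_binary = "T1-T2",
                              stage_binary = "I-II",
                              mesenchymal_binary = "non_mesenchymal"
                            )) {
  tie_method <- match.arg(tie_method)
  if (horizon <= 0) abort("`horizon` must be strictly positive.")
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` must lie in (0, 1).")
  structure(list(horizon = horizon, tie_method = tie_method,
                 ci_level = ci_level, min_stratum = min_stratum,
                 reference_levels = reference_levels),
            class = "survival_config")
}

#' Truncate and censor follow-up at a horizon
#'
#' Any time strictly greater than the horizon is replaced by the horizon
#' with the event flag cleared; times at or below the horizon are unchanged,
#' so an event at exactly the horizon is kept as an event.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Event indicators (0/1).
#' @param horizon Censoring horizon (default 36 months).
#' @return Tibble with `time` and `event` columns.
#' @examples
#' censor_at_horizon(c(40, 12, 36), c(1, 1, 1), 36)
#' @export
censor_at_horizon <- function(times, events, horizon = 36) {
  if (any(times < 0)) abort("Survival times must be non-negative.")
  if (!all(events %in% c(0, 1))) abort("`events` must be 0/1.")
  over <- times > horizon
  tibble(time = ifelse(over, horizon, times),
         event = as.integer(ifelse(over, 0L, events)))
}

#' Kaplan-Meier product-limit estimate
#'
#' Tidy step-function estimate of the survival curve, overall or per group.
#' At tied times, events are processed before censorings (the standard
#' product-limit convention). Without censoring the estimate equals the
#' empirical survivor function.
#'
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param group Optional group labels.
#' @return Tibble of class `"km_fit"`: `group` (if any), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, starting from a `time = 0`,
#'   `survival = 1` row per group.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (length(times) == 0) abort("Empty cohort.")
  df <- data.frame(time = times, event = events)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    out <- tibble(group = "all", time = c(0, fit$time),
                  n_risk = c(fit$n, fit$n.risk),
                  n_event = c(0, fit$n.event), n_censor = c(0, fit$n.censor),
                  survival = c(1, fit$surv))
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    out <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv)
    head0 <- out |> group_by(.data$group) |>
      summarise(n_risk = max(.data$n_risk), .groups = "drop") |>
      mutate(time = 0, n_event = 0, n_censor = 0, survival = 1)
    out <- dplyr::bind_rows(head0, out) |> arrange(.data$group, .data$time)
  }
  class(out) <- c("km_fit", class(out))
  out
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square statistic with G - 1 degrees
#' of freedom. With no events anywhere the statistic is 0 and p = 1.
#'
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return Tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) abort("Need >= 2 groups.")
  if (sum(events) == 0) {
    return(tibble(statistic = 0, df = length(unique(group)) - 1, p_value = 1,
                  method = "logrank"))
  }
  df <- data.frame(time = times, event = events, group = group)
  res <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(res$n) - 1
  tibble(statistic = res$chisq, df = dfree,
         p_value = pchisq(res$chisq, dfree, lower.tail = FALSE),
         method = "logrank")
}

#' Cox proportional-hazards fit with tidy hazard-ratio output
#'
#' Fits a partial-likelihood proportional-hazards model on the
#' horizon-censored cohort with the configured tie method. Categorical
#' covariates are releveled to the configured reference categories, and one
#' row per non-reference level is reported with the hazard ratio, Wald
#' confidence interval and p-value. Non-convergence or apparent complete
#' separation raises an explicit error.
#'
#' @param cohort Cohort tibble with `time` and `event` columns.
#' @param covariates Character vector of covariate column names.
#' @param config A [survival_config()].
#' @return Tibble of class `"cox_fit"`: `term`, `level`, `reference`, `n`,
#'   `n_events`, `hr`, `ci_low`, `ci_high`, `p_value`; the underlying
#'   `coxph` object is kept in attribute `fit`.
#' @export
cox_fit <- function(cohort, covariates, config = survival_config()) {
  if (!all(c("time", "event") %in% names(cohort))) {
    abort("`cohort` needs `time` and `event` columns.")
  }
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    abort(paste0("Unknown covariate(s): ", paste(missing_cov, collapse = ", ")))
  }
  cens <- censor_at_horizon(cohort$time, cohort$event, config$horizon)
  df <- cohort
  df$time <- cens$time
  df$event <- cens$event
  df <- df[complete.cases(df[, c("time", "event", covariates)]), , drop = FALSE]

  refs <- character(0)
  for (v in covariates) {
    if (!is.numeric(df[[v]])) {
      lev <- unique(as.character(df[[v]]))
      if (length(lev) < 2) abort(paste0("Covariate ", v, " has < 2 observed levels."))
      ref <- config$reference_levels[[v]] %||% sort(lev)[1]
      if (!ref %in% lev) ref <- sort(lev)[1]
      df[[v]] <- stats::relevel(factor(df[[v]]), ref = ref)
      refs[v] <- ref
    } else {
      refs[v] <- ""
    }
  }
  n_events <- sum(df$event)
  if (n_events < length(covariates)) {
    abort("Fewer events than model parameters; fit is not identified.")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = config$tie_method),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        abort(paste0("Cox fit did not converge (possible complete separation): ",
                     conditionMessage(w)))
      }
      suppressWarnings(survival::coxph(fml, data = df, ties = config$tie_method))
    }
  )
  if (any(!is.finite(fit$coefficients)) || any(abs(fit$coefficients) > 15)) {
    abort("Cox fit produced non-finite or diverging coefficients (complete separation?).")
  }
  s <- summary(fit, conf.int = config$ci_level)
  terms_used <- names(fit$coefficients)
  term_of <- function(nm) covariates[which.max(startsWith(nm, covariates))]
  term_col <- unname(vapply(terms_used, term_of, character(1)))
  out <- tibble(
    term = term_col,
    level = unname(mapply(function(nm, tm) sub(paste0("^", tm), "", nm),
                          terms_used, term_col)),
    n = nrow(df), n_events = n_events,
    hr = unname(s$conf.int[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, 3]), ci_high = unname(s$conf.int[, 4]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"])
  )
  out$reference <- unname(refs[out$term])
  out$level[out$level == ""] <- "per unit"
  out <- out[, c("term", "level", "reference", "n", "n_events", "hr",
                 "ci_low", "ci_high", "p_value")]
  class(out) <- c("cox_fit", class(out))
  attr(out, "fit") <- fit
  out
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cox_fit")
  attr(out, "fit") <- NULL
  out
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(n = unique(x$n), n_events = unique(x$n_events),
         concordance = unname(fit$concordance["concordance"]),
         loglik = fit$loglik[2])
}

# Binary recodes used by the stratified report.
add_survival_groupings <- function(cohort) {
  cohort <- derive_cohort_columns(cohort)
  if ("T_stage" %in% names(cohort)) {
    cohort$t_binary <- ifelse(cohort$T_stage %in% c("T1", "T2"),
                              "T1-T2", "T3-T4")
  }
  if ("overall_stage" %in% names(cohort)) {
    cohort$stage_binary <- ifelse(cohort$overall_stage %in% c("I", "II"),
                                  "I-II", "III-IV")
  }
  if (all(c("mesenchymal_binary", "node_binary") %in% names(cohort))) {
    cohort$subtype_node_group <- paste(cohort$mesenchymal_binary,
                                       cohort$node_binary, sep = "/")
  }
  cohort
}

# Median split of age, labelled with the observed range below the median
# (e.g. "19-61"), which becomes the reference category.
dichotomize_age <- function(cohort) {
  med <- median(cohort$age, na.rm = TRUE)
  low <- cohort$age <= med
  low_lab <- paste0(min(cohort$age[low], na.rm = TRUE), "-",
                    max(cohort$age[low], na.rm = TRUE))
  high_lab <- paste0(">", max(cohort$age[low], na.rm = TRUE))
  cohort$age_binary <- ifelse(low, low_lab, high_lab)
  attr(cohort, "age_reference") <- low_lab
  cohort
}

#' Stratified survival report over the cohort's clinical subgroups
#'
#' Reproduces the stratified analysis layout for a subtyped cohort:
#' univariate Cox fits within the oral-cavity N0 and N+ strata for gender,
#' smoking, HPV status, radiation, T stage (T1-T2 vs T3-T4), overall stage
#' (I-II vs III-IV), mesenchymal subtype and median-split age; multivariate
#' fits of T stage + subtype (N0 stratum) and subtype + age (N+ stratum);
#' and Kaplan-Meier curves with log-rank tests for the four
#' subtype-by-node groups within the oral-cavity, non-oral-cavity and
#' non-oral-cavity HPV-negative subsets. Strata smaller than
#' `config$min_stratum` are flagged in the output rather than dropped.
#'
#' @param cohort Cohort tibble with clinical fields, subtype calls, `time`
#'   and `event`.
#' @param config A [survival_config()].
#' @return List of class `"subgroup_survival"` with `cox_table` (tidy rows:
#'   `stratum`, `analysis`, `term`, `level`, `reference`, `n`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `flag`), `km_curves` (per-subset
#'   `km_fit` tibbles) and `logrank` (per-subset log-rank results).
#' @export
subgroup_survival_analysis <- function(cohort, config = survival_config()) {
  cohort <- add_survival_groupings(cohort)
  cohort <- dichotomize_age(cohort)
  age_ref <- attr(cohort, "age_reference")
  config$reference_levels$age_binary <- age_ref

  uni_vars <- c("gender", "smoker", "hpv", "radiation", "t_binary",
                "stage_binary", "mesenchymal_binary", "age_binary")
  strata <- list(
    "oral_cavity_N0" = cohort$site_group == "oral_cavity" & cohort$node_binary == "N0",
    "oral_cavity_N+" = cohort$site_group == "oral_cavity" & cohort$node_binary == "N+"
  )
  multi_vars <- list(
    "oral_cavity_N0" = c("t_binary", "mesenchymal_binary"),
    "oral_cavity_N+" = c("mesenchymal_binary", "age_binary")
  )

  rows <- list()
  for (st in names(strata)) {
    sub <- cohort[strata[[st]], , drop = FALSE]
    flag <- if (nrow(sub) < config$min_stratum)
      paste0("small stratum (n=", nrow(sub), ")") else NA_character_
    for (v in intersect(uni_vars, names(sub))) {
      res <- tryCatch(cox_fit(sub, v, config), error = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1]] <- tibble(
          stratum = st, analysis = "univariate", term = v, level = NA,
          reference = NA, n = nrow(sub), hr = NA, ci_low = NA, ci_high = NA,
          p_value = NA, flag = "fit failed")
        next
      }
      rows[[length(rows) + 1]] <- tidy(res) |>
        mutate(stratum = st, analysis = "univariate", flag = flag) |>
        select("stratum", "analysis", "term", "level", "reference", "n",
               "hr", "ci_low", "ci_high", "p_value", "flag")
    }
    mv <- intersect(multi_vars[[st]], names(sub))
    res <- tryCatch(cox_fit(sub, mv, config), error = function(e) NULL)
    if (!is.null(res)) {
      rows[[length(rows) + 1]] <- tidy(res) |>
        mutate(stratum = st, analysis = "multivariate", flag = flag) |>
        select("stratum", "analysis", "term", "level", "reference", "n",
               "hr", "ci_low", "ci_high", "p_value", "flag")
    }
  }
  cox_table <- dplyr::bind_rows(rows)

  km_sets <- list(
    oral_cavity = cohort$site_group == "oral_cavity",
    non_oral_cavity = cohort$site_group == "non_oral_cavity",
    non_oral_cavity_hpv_negative =
      cohort$site_group == "non_oral_cavity" & cohort$hpv == "negative"
  )
  km_curves <- list()
  logrank <- list()
  for (nm in names(km_sets)) {
    sub <- cohort[km_sets[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) next
    cens <- censor_at_horizon(sub$time, sub$event, config$horizon)
    km_curves[[nm]] <- km_estimate(cens$time, cens$event,
                                   group = sub$subtype_node_group)
    lr <- logrank_test(cens$time, cens$event, sub$subtype_node_group)
    lr$subset <- nm
    lr$n <- nrow(sub)
    lr$flag <- if (any(table(sub$subtype_node_group) < config$min_stratum))
      "small group(s)" else NA_character_
    logrank[[nm]] <- lr
  }
  structure(list(cox_table = cox_table, km_curves = km_curves,
                 logrank = dplyr::bind_rows(logrank)),
            class = "subgroup_survival")
}

#' @export
print.subgroup_survival <- function(x, ...) {
  cat("<subgroup_survival>\n")
  cat("  Cox rows:", nrow(x$cox_table), "| KM subsets:",
      length(x$km_curves), "\n")
  invisible(x)
}

#' @method tidy subgroup_survival
#' @export
tidy.subgroup_survival <- function(x, ...) x$cox_table
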