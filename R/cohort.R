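# Cohort-table utilities and association statistics.

#' Derive standard binary cohort columns
#'
#' Adds (or refreshes) the derived grouping columns used throughout the
#' analysis: `node_binary` (`"N+"` for N1/N2/N3, `"N0"` otherwise),
#' `mesenchymal_binary` (`"mesenchymal"` vs `"non_mesenchymal"`),
#' `site_group` (`"oral_cavity"` vs `"non_oral_cavity"`) and
#' `overall_stage` from T and N stage when absent (N+ implies stage III/IV;
#' N0 maps T1..T4 to I..IV).
#'
#' @param cohort Cohort tibble with `N_stage` and/or `subtype`, `site`,
#'   `T_stage` columns as available.
#' @return The cohort with derived columns added.
#' @export
derive_cohort_columns <- function(cohort) {
  if ("N_stage" %in% names(cohort)) {
    cohort$node_binary <- ifelse(cohort$N_stage %in% c("N1", "N2", "N3"),
                                 "N+", "N0")
  }
  if ("subtype" %in% names(cohort)) {
    cohort$mesenchymal_binary <- ifelse(cohort$subtype == "mesenchymal",
                                        "mesenchymal", "non_mesenchymal")
  }
  if ("site" %in% names(cohort)) {
    cohort$site_group <- ifelse(cohort$site == "oral_cavity",
                                "oral_cavity", "non_oral_cavity")
  }
  if (!"overall_stage" %in% names(cohort) &&
      all(c("T_stage", "N_stage") %in% names(cohort))) {
    t_num <- as.integer(sub("T", "", cohort$T_stage))
    node_pos <- cohort$node_binary == "N+"
    stage <- c("I", "II", "III", "IV")[t_num]
    stage[node_pos & cohort$N_stage == "N1" & t_num <= 3] <- "III"
    stage[node_pos & (cohort$N_stage != "N1" | t_num == 4)] <- "IV"
    cohort$overall_stage <- stage
  }
  cohort
}

#' Published TCGA HNSCC stratum counts
#'
#' Per-stratum sample counts from a published TCGA head and neck squamous
#' cell carcinoma cohort (n = 418): stratum sizes by anatomic-site group,
#' nodal status and mesenchymal-versus-other subtype, plus the oral-cavity
#' T-stage breakdowns. These printed counts let the cohort's contingency
#' claims (nodal-positivity fractions by subtype, T-stage by nodal status)
#' be recomputed without access to the underlying clinical data.
#'
#' @return Tidy tibble with columns `site_group`, `node`, `subtype_group`,
#'   `variable`, `level`, `count`.
#' @examples
#' counts <- published_cohort_counts()
#' sum(counts$count[counts$variable == "total"]) # 418
#' @export
published_cohort_counts <- function() {
  path <- system.file("extdata", "tcga_hnscc_stratum_counts.tsv",
                      package = "hnsubtype", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Cross-tabulate two categorical cohort variables
#'
#' Builds an integer contingency table over non-missing pairs, optionally
#' within a stratum. Rows dropped for missingness are reported via a
#' message and the `n_missing` attribute, never silently.
#'
#' @param cohort Cohort tibble.
#' @param row_var,col_var Variable names (strings).
#' @param filter Optional logical expression evaluated in the cohort,
#'   selecting the stratum (e.g. `site_group == "oral_cavity"`).
#' @return A base `table` of counts with `n_missing` attribute.
#' @export
build_contingency <- function(cohort, row_var, col_var, filter = NULL) {
  for (v in c(row_var, col_var)) {
    if (!v %in% names(cohort)) abort(paste0("Unknown variable: ", v))
  }
  f <- rlang::enquo(filter)
  if (!rlang::quo_is_null(f)) {
    cohort <- dplyr::filter(cohort, !!f)
  }
  if (nrow(cohort) == 0) abort("The selected stratum is empty.")
  ok <- !is.na(cohort[[row_var]]) & !is.na(cohort[[col_var]])
  n_missing <- sum(!ok)
  if (n_missing > 0) {
    inform(paste0(n_missing, " sample(s) excluded for missing ",
                  row_var, "/", col_var, "."))
  }
  tab <- table(cohort[[row_var]][ok], cohort[[col_var]][ok],
               dnn = c(row_var, col_var))
  if (any(dim(tab) < 2)) abort("Contingency table must be at least 2x2.")
  attr(tab, "n_missing") <- n_missing
  tab
}

#' Pearson chi-square test of independence
#'
#' Wraps the standard chi-square test with `(r-1)(c-1)` degrees of freedom;
#' the continuity correction is off by default so 2x2 results match the
#' uncorrected statistic.
#'
#' @param tab Contingency table (matrix or `table`).
#' @param continuity_correction Apply Yates' correction (default `FALSE`).
#' @return Tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_test <- function(tab, continuity_correction = FALSE) {
  tab <- as.matrix(tab)
  if (any(!is.finite(tab))) abort("All cells must be finite.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Chi-square test undefined for a zero margin.")
  }
  res <- suppressWarnings(chisq.test(tab, correct = continuity_correction))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, method = "chi_square")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table, with the conditional odds ratio.
#'
#' @param tab 2x2 contingency table.
#' @return Tibble with `odds_ratio`, `p_value`, `method`.
#' @export
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("Fisher's exact test requires a 2x2 table.")
  res <- fisher.test(tab)
  tibble(odds_ratio = unname(res$estimate), p_value = res$p.value,
         method = "fisher_exact")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic against a chi-square reference. When every
#' value is identical the statistic is 0 with p = 1 (no rank information).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) abort("`values` and `groups` must align.")
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    abort("Need >= 2 non-empty groups.")
  }
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = nlevels(groups) - 1, p_value = 1,
                  method = "kruskal_wallis"))
  }
  res <- kruskal.test(values, groups)
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, method = "kruskal_wallis")
}

#' Association test under the default policy
#'
#' For a 2x2 table, runs the Pearson chi-square test (no correction) when
#' every expected count is at least 5 and Fisher's exact test otherwise —
#' an explicit, configurable mapping since published reports often name
#' both tests without saying which produced which p-value. With
#' `policy = "both"` the result has one row per test.
#'
#' @param tab Contingency table.
#' @param policy `"auto"` (default), `"chi_square"`, `"fisher"`, `"both"`.
#' @return Tibble with one row per test performed.
#' @export
test_association <- function(tab, policy = c("auto", "chi_square", "fisher", "both")) {
  policy <- match.arg(policy)
  tab <- as.matrix(tab)
  is2x2 <- all(dim(tab) == c(2, 2))
  if (policy == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    policy <- if (all(expected >= 5) || !is2x2) "chi_square" else "fisher"
  }
  out <- list()
  if (policy %in% c("chi_square", "both")) out$chi <- chi_square_test(tab)
  if (policy %in% c("fisher", "both") && is2x2) out$fisher <- fisher_exact_test(tab)
  dplyr::bind_rows(out)
}

#' Descriptive cohort summary by stratum
#'
#' Summarises the cohort within each site-group x nodal-status x
#' mesenchymal-status stratum: counts and within-stratum percentages for
#' each categorical variable (computed over non-missing values) and the
#' median for age. Percentages are also rounded to whole percent in
#' `pct_label`, with full precision kept in `pct`.
#'
#' @param cohort Cohort tibble (with derived columns; see
#'   [derive_cohort_columns()]).
#' @param categorical Character vector of categorical variables to
#'   summarise.
#' @return Tidy tibble: stratum columns, `variable`, `level`, `n`, `pct`,
#'   `pct_label` (categorical rows) and `median` (age rows).
#' @export
descriptive_table <- function(cohort,
                              categorical = c("site", "gender", "smoker", "hpv",
                                              "radiation", "T_stage", "N_stage",
                                              "overall_stage", "subtype")) {
  cohort <- derive_cohort_columns(cohort)
  strata <- c("site_group", "node_binary", "mesenchymal_binary")
  if (!all(strata %in% names(cohort))) {
    abort("Cohort must carry site_group, node_binary and mesenchymal_binary.")
  }
  categorical <- intersect(categorical, names(cohort))
  cat_rows <- purrr::map_dfr(categorical, function(v) {
    cohort |>
      filter(!is.na(.data[[v]])) |>
      group_by(dplyr::across(dplyr::all_of(strata)), level = .data[[v]]) |>
      summarise(n = dplyr::n(), .groups = "drop_last") |>
      mutate(variable = v, pct = 100 * .data$n / sum(.data$n),
             pct_label = paste0(round(.data$pct), "%")) |>
      ungroup()
  })
  age_rows <- NULL
  if ("age" %in% names(cohort)) {
    age_rows <- cohort |>
      filter(!is.na(.data$age)) |>
      group_by(dplyr::across(dplyr::all_of(strata))) |>
      summarise(median = median(.data$age), .groups = "drop") |>
      mutate(variable = "age", level = "median")
  }
  dplyr::bind_rows(cat_rows, age_rows) |>
    select(dplyr::all_of(strata), "variable", "level",
           dplyr::any_of(c("n", "pct", "pct_label", "median"))) |>
    arrange(.data$site_group, .data$node_binary, .data$mesenchymal_binary,
            .data$variable, .data$level)
}

#' Read / write a cohort table TSV
#'
#' Column dictionary: `sample_id`; `site` (oral_cavity / larynx /
#' oropharynx / hypopharynx); `T_stage` (T1-T4); `N_stage` (N0-N3);
#' `overall_stage` (I-IV); `age` (years); `gender` (M/F); `smoker`
#' (yes/no); `hpv` (positive/negative); `radiation` (yes/no); `subtype`;
#' `time` (months); `event` (0/1). Derived columns are recomputed on read.
#'
#' @param path File path.
#' @return `read_cohort_tsv()` returns a cohort tibble.
#' @export
read_cohort_tsv <- function(path) {
  derive_cohort_columns(as_tibble(read.delim(path, stringsAsFactors = FALSE)))
}

#' @rdname read_cohort_tsv
#' @param cohort Cohort tibble.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
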