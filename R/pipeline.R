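# End-to-end orchestration: file-based commands mirroring the analysis
# stages (simulate -> train -> classify -> hpv-call -> analyze). Each
# command writes its outputs plus a manifest with the seed and file
# checksums so reruns are auditable. inst/cli/hnsubtype.R exposes these as
# shell subcommands.

file_checksum <- function(path) {
  as.character(tools::md5sum(path))
}

write_manifest <- function(out_dir, command, seed, files) {
  manifest <- data.frame(
    command = command, seed = seed, file = basename(files),
    md5 = vapply(files, file_checksum, character(1)),
    row.names = NULL
  )
  path <- file.path(out_dir, paste0(command, "_manifest.tsv"))
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Writes four TSVs (expression matrix, clinical table, HPV counts, true
#' labels) plus a manifest recording the seed and file checksums.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of the written file paths.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  files <- c(
    expression = file.path(out_dir, "expression.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    hpv_counts = file.path(out_dir, "hpv_counts.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_expression_tsv(sim$expression, files["expression"])
  write_cohort_tsv(sim$cohort, files["clinical"])
  write.table(sim$hpv_counts, files["hpv_counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(out_dir, "simulate", config$seed, files)
  invisible(files)
}

#' Train the reduced classifier from files
#'
#' @param expression_path Log2-scale expression TSV (gene x sample).
#' @param gold_path Either a serialized gold centroid model (TSV from
#'   [write_centroid_model()]) or a gold-call table with `sample_id`,
#'   `subtype` and `call_strength` columns.
#' @param config A [training_config()].
#' @param out_dir Output directory.
#' @param candidate_sizes Optional sizes for the cross-validation curve.
#' @return Invisibly, the fitted `reduced_classifier_fit`.
#' @export
cmd_train <- function(expression_path, gold_path, config = training_config(),
                      out_dir = ".", candidate_sizes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- read_expression_tsv(expression_path, scale = "log2")
  first <- readLines(gold_path, n = 1)
  if (grepl("^# centroid_model", first)) {
    gold_model <- read_centroid_model(gold_path)
    fit <- build_reduced_classifier(expr, gold_model, config,
                                    candidate_sizes = candidate_sizes)
  } else {
    gold_calls <- as_tibble(read.delim(gold_path, stringsAsFactors = FALSE))
    fit <- build_reduced_classifier(expr, gold_model = NULL, config = config,
                                    candidate_sizes = candidate_sizes,
                                    gold_calls = gold_calls)
  }
  files <- c(model = file.path(out_dir, "reduced_model.tsv"),
             cv = file.path(out_dir, "cv_report.tsv"))
  write_centroid_model(fit$model, files["model"])
  write.table(fit$cv_report, files["cv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(out_dir, "train", config$seed, files)
  invisible(fit)
}

#' Classify samples from files
#'
#' @param expression_path Log2-scale expression TSV.
#' @param model_path Serialized centroid model TSV.
#' @param out_path Output calls TSV (`sample_id`, `subtype`, distances,
#'   `call_strength`).
#' @return Invisibly, the calls tibble.
#' @export
cmd_classify <- function(expression_path, model_path,
                         out_path = "subtype_calls.tsv") {
  expr <- read_expression_tsv(expression_path, scale = "log2")
  model <- read_centroid_model(model_path)
  calls <- classify_samples(expr, model)
  write.table(calls, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Call HPV status from a count file
#'
#' @param counts_path TSV with `sample_id` and the four HPV type columns.
#' @param out_path Output status TSV.
#' @param threshold Calling threshold (default 1000 counts).
#' @return Invisibly, the status tibble.
#' @export
cmd_hpv_call <- function(counts_path, out_path = "hpv_status.tsv",
                         threshold = 1000) {
  counts <- read_hpv_counts(counts_path)
  calls <- call_hpv_status(counts, threshold = threshold)
  write_hpv_calls(calls, out_path)
  invisible(calls)
}

#' Run the full clinical analysis from files
#'
#' Joins clinical data, subtype calls and HPV status, then writes the
#' descriptive stratum summary, the association tests (mesenchymal status
#' vs nodal status overall; T stage vs nodal status within the
#' oral-cavity mesenchymal and non-mesenchymal groups), the stratified Cox
#' report and the Kaplan-Meier step functions.
#'
#' @param clinical_path Cohort TSV (see [read_cohort_tsv()] for columns).
#' @param calls_path Subtype-call TSV from [cmd_classify()].
#' @param hpv_path Optional HPV status TSV from [cmd_hpv_call()]; when
#'   given, it overrides any `hpv` column in the clinical table.
#' @param config A [survival_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `descriptive`, `associations`, and the
#'   `subgroup_survival` result.
#' @export
cmd_analyze <- function(clinical_path, calls_path, hpv_path = NULL,
                        config = survival_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort_tsv(clinical_path)
  calls <- as_tibble(read.delim(calls_path, stringsAsFactors = FALSE))
  if (!all(c("sample_id", "subtype") %in% names(calls))) {
    abort("Calls file must have `sample_id` and `subtype` columns.")
  }
  cohort$subtype <- NULL
  cohort <- dplyr::left_join(cohort, calls[, c("sample_id", "subtype")],
                             by = "sample_id")
  if (anyNA(cohort$subtype)) abort("Some samples lack a subtype call.")
  if (!is.null(hpv_path)) {
    hpv <- as_tibble(read.delim(hpv_path, stringsAsFactors = FALSE))
    cohort$hpv <- NULL
    cohort <- dplyr::left_join(cohort, hpv[, c("sample_id", "hpv")],
                               by = "sample_id")
  }
  required <- c("site", "N_stage", "time", "event")
  miss <- setdiff(required, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("Clinical table is missing field(s): ",
                 paste(miss, collapse = ", ")))
  }
  cohort <- derive_cohort_columns(cohort)

  desc <- descriptive_table(cohort)
  assoc <- dplyr::bind_rows(
    test_association(build_contingency(cohort, "mesenchymal_binary",
                                       "node_binary"), "both") |>
      mutate(comparison = "mesenchymal_vs_node", stratum = "all"),
    test_association(
      build_contingency(add_survival_groupings(cohort), "t_binary", "node_binary",
                        filter = .data$site_group == "oral_cavity" &
                          .data$mesenchymal_binary == "mesenchymal"), "both") |>
      mutate(comparison = "t_stage_vs_node", stratum = "oral_cavity_mesenchymal"),
    test_association(
      build_contingency(add_survival_groupings(cohort), "t_binary", "node_binary",
                        filter = .data$site_group == "oral_cavity" &
                          .data$mesenchymal_binary == "non_mesenchymal"), "both") |>
      mutate(comparison = "t_stage_vs_node", stratum = "oral_cavity_non_mesenchymal")
  )
  surv <- subgroup_survival_analysis(cohort, config)

  write.table(desc, file.path(out_dir, "descriptive_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(assoc, file.path(out_dir, "association_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(surv$cox_table, file.path(out_dir, "cox_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(surv$logrank, file.path(out_dir, "logrank_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  km_all <- dplyr::bind_rows(lapply(names(surv$km_curves), function(nm) {
    out <- surv$km_curves[[nm]]
    out$subset <- nm
    out
  }))
  write.table(km_all, file.path(out_dir, "km_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(descriptive = desc, associations = assoc, survival = surv))
}

#' Run the complete pipeline on a synthetic cohort
#'
#' simulate -> gold-model training on true labels -> reduced-classifier
#' training -> classification -> HPV calling -> clinical analysis, all
#' under one seed, writing every artefact to `out_dir`.
#'
#' @param sim A [sim_config()].
#' @param train A [training_config()].
#' @param surv A [survival_config()].
#' @param out_dir Output directory.
#' @param gold_total_genes Size of the gold model trained on the true
#'   labels (defaults to all marker genes).
#' @return Invisibly, a list of the in-memory results.
#' @export
cmd_all <- function(sim = sim_config(), train = training_config(),
                    surv = survival_config(), out_dir = ".",
                    gold_total_genes = NULL) {
  files <- cmd_simulate(sim, out_dir)
  expr <- read_expression_tsv(files["expression"], scale = "log2")
  truth <- as_tibble(read.delim(files["truth"], stringsAsFactors = FALSE))
  gold_size <- gold_total_genes %||% (4 * sim$n_marker_genes_per_subtype)
  gold <- train_centroid_model(expr, truth[, c("sample_id", "subtype")],
                               total_genes = gold_size, q = 0,
                               sd_floor = train$sd_floor)
  write_centroid_model(gold, file.path(out_dir, "gold_model.tsv"))
  fit <- cmd_train(files["expression"], file.path(out_dir, "gold_model.tsv"),
                   config = train, out_dir = out_dir)
  calls <- cmd_classify(files["expression"],
                        file.path(out_dir, "reduced_model.tsv"),
                        file.path(out_dir, "subtype_calls.tsv"))
  hpv <- cmd_hpv_call(files["hpv_counts"], file.path(out_dir, "hpv_status.tsv"))
  analysis <- cmd_analyze(files["clinical"],
                          file.path(out_dir, "subtype_calls.tsv"),
                          file.path(out_dir, "hpv_status.tsv"),
                          config = surv, out_dir = out_dir)
  invisible(list(files = files, gold = gold, fit = fit, calls = calls,
                 hpv = hpv, analysis = analysis))
}
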