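#' Configuration for balanced-centroid training
#'
#' Defaults follow the published reduced-model design: an 88-gene model
#' (22 genes per subtype, 11 high + 11 low for K = 4), exclusion of the 20%
#' of training samples per subtype with the lowest gold-standard call
#' strength, fivefold cross-validation for size selection, and a candidate
#' pool of the gold-standard genes plus up to 348 additional high-mean,
#' high-variance genes.
#'
#' @param total_genes Model size; must be divisible by `2 * K` at training
#'   time (default 88).
#' @param exclusion_fraction Fraction `q` of lowest-call-strength samples
#'   excluded per subtype when computing coefficients (default 0.20).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param candidate_extra_genes Cap on additional high-mean/high-variance
#'   candidate genes beyond the gold-standard set (default 348).
#' @param sd_floor Pooled-standard-deviation floor for the per-class
#'   statistics (default 0.05 log2 units).
#' @param agreement_tol Size-selection rule: the smallest candidate size
#'   whose mean CV agreement is within this tolerance of the maximum is
#'   chosen (default 0.01).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(total_genes = 88, exclusion_fraction = 0.20,
                            cv_folds = 5, candidate_extra_genes = 348,
                            sd_floor = 0.05, agreement_tol = 0.01, seed = 1L) {
  if (exclusion_fraction < 0 || exclusion_fraction >= 1) {
    abort("`exclusion_fraction` must lie in [0, 1).")
  }
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  if (total_genes < 2) abort("`total_genes` must be >= 2.")
  if (candidate_extra_genes < 0) abort("`candidate_extra_genes` must be >= 0.")
  structure(list(total_genes = as.integer(total_genes),
                 exclusion_fraction = exclusion_fraction,
                 cv_folds = as.integer(cv_folds),
                 candidate_extra_genes = as.integer(candidate_extra_genes),
                 sd_floor = sd_floor, agreement_tol = agreement_tol,
                 seed = as.integer(seed)),
            class = "training_config")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# cyclically so fold sizes differ by at most one per class.
make_stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated agreement across candidate model sizes
#'
#' For each candidate size, trains the balanced-centroid pipeline
#' (statistics, balanced selection, median centroids with call-strength
#' exclusion) on each training split — using the gold-standard calls as
#' labels — classifies the held-out split, and records agreement with the
#' gold calls. Folds are stratified by gold call and seeded.
#'
#' @param expr Log2-scale expression tibble (already restricted to the
#'   candidate gene pool).
#' @param gold_calls Tibble with `sample_id`, `subtype` and `call_strength`
#'   (as returned by [classify_samples()] under the gold model).
#' @param candidate_sizes Integer vector of model sizes, each divisible by
#'   `2 * K`.
#' @param config A [training_config()].
#' @return Tibble with one row per size: `size`, `mean_agreement`,
#'   `sd_agreement`; per-fold agreements are kept in attribute `per_fold`.
#' @export
cross_validate_size <- function(expr, gold_calls, candidate_sizes, config) {
  values <- as_expression_matrix(expr)
  ord <- match(colnames(values), gold_calls$sample_id)
  if (anyNA(ord)) abort("`gold_calls` must cover every sample column.")
  labels <- gold_calls$subtype[ord]
  strengths <- gold_calls$call_strength[ord]
  classes <- label_classes(labels)
  k <- length(classes)
  bad <- candidate_sizes[candidate_sizes %% (2 * k) != 0]
  if (length(bad) > 0) {
    abort(paste0("Candidate size(s) not divisible by 2K: ",
                 paste(bad, collapse = ", ")))
  }
  folds <- make_stratified_folds(labels, config$cv_folds, config$seed)

  per_fold <- purrr::map_dfr(candidate_sizes, function(size) {
    purrr::map_dfr(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      if (length(unique(labels[tr])) < k || length(unique(labels[!tr])) < 1) {
        abort(paste0("Fold ", f, " is missing a subtype; increase n or reduce folds."))
      }
      tr_expr <- expression_tibble(values[, tr, drop = FALSE], scale = "log2")
      model <- train_centroid_model(tr_expr, labels[tr], total_genes = size,
                                    strengths = strengths[tr],
                                    q = config$exclusion_fraction,
                                    sd_floor = config$sd_floor)
      te_expr <- expression_tibble(values[, !tr, drop = FALSE], scale = "log2")
      calls <- classify_samples(te_expr, model)
      tibble(size = size, fold = f,
             agreement = mean(calls$subtype == labels[!tr]))
    })
  })
  out <- per_fold |>
    group_by(.data$size) |>
    summarise(mean_agreement = mean(.data$agreement),
              sd_agreement = sd(.data$agreement), .groups = "drop")
  attr(out, "per_fold") <- per_fold
  out
}

# Candidate pool: all gold-model genes present in the matrix, plus the
# highest-variance genes among those with above-median mean expression
# ("high observed mean and variance"), capped at `extra`.
candidate_gene_pool <- function(expr, gold_genes, extra) {
  values <- as_expression_matrix(expr)
  gold_present <- intersect(gold_genes, rownames(values))
  pool <- gold_present
  if (extra > 0) {
    means <- rowMeans(values)
    vars <- apply(values, 1, stats::var)
    eligible <- setdiff(rownames(values)[means > median(means)], gold_present)
    eligible <- eligible[order(-vars[eligible], eligible)]
    pool <- c(gold_present, head(eligible, extra))
  }
  pool
}

#' Build the reduced balanced-centroid classifier
#'
#' The full reduced-model construction: classify all samples with the gold
#' model to obtain labels and call strengths; form the candidate pool (gold
#' genes plus up to `candidate_extra_genes` high-mean/high-variance genes);
#' estimate cross-validated agreement with the gold calls across the
#' candidate sizes; choose the smallest size within `agreement_tol` of the
#' best; and fit the final model on all samples, excluding the
#' lowest-call-strength fraction per subtype.
#'
#' @param expr Log2-scale expression tibble.
#' @param gold_model The gold-standard `centroid_model` (or pre-computed
#'   gold calls via `gold_calls`).
#' @param config A [training_config()].
#' @param candidate_sizes Sizes to evaluate by cross-validation; defaults to
#'   `config$total_genes` alone (the published fixed size).
#' @param gold_calls Optional tibble of gold calls (`sample_id`, `subtype`,
#'   `call_strength`); computed from `gold_model` when absent.
#' @return A list of class `"reduced_classifier_fit"` with elements `model`
#'   (the fitted `centroid_model`), `cv_report`, `chosen_size`,
#'   `gold_calls`, and `candidate_pool`.
#' @examples
#' sim <- simulate_expression(sim_config(n_samples = 60, seed = 5))
#' gold <- train_centroid_model(sim$expression, sim$labels, total_genes = 40)
#' fit <- build_reduced_classifier(sim$expression, gold,
#'                                 training_config(total_genes = 8, seed = 5))
#' glance(fit)
#' @export
build_reduced_classifier <- function(expr, gold_model = NULL,
                                     config = training_config(),
                                     candidate_sizes = NULL,
                                     gold_calls = NULL) {
  if (is.null(gold_calls)) {
    if (is.null(gold_model)) abort("Provide `gold_model` or `gold_calls`.")
    gold_calls <- classify_samples(expr, gold_model)
  }
  gold_genes <- if (!is.null(gold_model)) gold_model$genes else character(0)
  pool <- candidate_gene_pool(expr, gold_genes, config$candidate_extra_genes)
  pool_expr <- align_genes(expr, pool, min_present_fraction = 1)
  pool_expr <- set_expr_scale(pool_expr, "log2")

  sizes <- candidate_sizes %||% config$total_genes
  cv_report <- cross_validate_size(pool_expr, gold_calls, sizes, config)
  best <- max(cv_report$mean_agreement)
  chosen <- min(cv_report$size[cv_report$mean_agreement >= best - config$agreement_tol])

  labels <- gold_calls$subtype
  names(labels) <- gold_calls$sample_id
  stats <- clanc_statistics(pool_expr, gold_calls[, c("sample_id", "subtype")],
                            sd_floor = config$sd_floor)
  selection <- select_balanced_genes(stats, chosen)
  model <- compute_centroids(pool_expr, gold_calls[, c("sample_id", "subtype")],
                             selection,
                             strengths = gold_calls[, c("sample_id", "call_strength")],
                             q = config$exclusion_fraction,
                             classes = attr(stats, "classes"))
  structure(list(model = model, cv_report = cv_report, chosen_size = chosen,
                 gold_calls = gold_calls, candidate_pool = pool),
            class = "reduced_classifier_fit")
}

#' @export
print.reduced_classifier_fit <- function(x, ...) {
  cat("<reduced_classifier_fit>\n")
  cat("  chosen size:", x$chosen_size, "genes\n")
  cat("  candidate pool:", length(x$candidate_pool), "genes\n")
  print(x$model)
  invisible(x)
}

#' Tidy the cross-validation report of a reduced-classifier fit
#' @param x A `reduced_classifier_fit`.
#' @param ... Unused.
#' @return The CV report tibble (`size`, `mean_agreement`, `sd_agreement`).
#' @method tidy reduced_classifier_fit
#' @export
tidy.reduced_classifier_fit <- function(x, ...) x$cv_report

#' One-row summary of a reduced-classifier fit
#' @param x A `reduced_classifier_fit`.
#' @param ... Unused.
#' @return Tibble with `chosen_size`, `n_candidates`, `cv_agreement`.
#' @method glance reduced_classifier_fit
#' @export
glance.reduced_classifier_fit <- function(x, ...) {
  tibble(chosen_size = x$chosen_size,
         n_candidates = length(x$candidate_pool),
         cv_agreement = x$cv_report$mean_agreement[x$cv_report$size == x$chosen_size])
}

#' Train a binary nodal-positivity predictor
#'
#' Reuses the balanced-centroid machinery with K = 2 (classes N0 / N+) to
#' predict lymph-node positivity from expression, reporting both
#' resubstitution accuracy and stratified cross-validated accuracy. The
#' mechanism mirrors published expression-based node predictors; no claim is
#' made about feature counts used elsewhere.
#'
#' @param expr Log2-scale expression tibble.
#' @param node_status Per-sample status: vector of `"N0"`/`"N+"` aligned
#'   with sample columns, or a tibble with `sample_id` and `node_binary`.
#' @param config A [training_config()]; `total_genes` must be divisible
#'   by 4.
#' @return List of class `"node_predictor_fit"`: `model`, `train_accuracy`,
#'   `cv_accuracy`.
#' @export
train_binary_node_predictor <- function(expr, node_status,
                                        config = training_config(total_genes = 40)) {
  prep <- check_labels(expr, node_status)
  labels <- prep$labels
  if (!setequal(unique(labels), c("N0", "N+"))) {
    abort("`node_status` must contain both classes N0 and N+.")
  }
  if (config$total_genes %% 4 != 0) {
    abort("`total_genes` must be divisible by 4 for a binary predictor.")
  }
  values <- prep$values
  full_expr <- expression_tibble(values, scale = "log2")
  model <- train_centroid_model(full_expr, labels,
                                total_genes = config$total_genes,
                                q = 0, sd_floor = config$sd_floor)
  resub <- classify_samples(full_expr, model)
  train_acc <- mean(resub$subtype == labels)

  folds <- make_stratified_folds(labels, config$cv_folds, config$seed)
  cv_hits <- purrr::map_dbl(seq_len(config$cv_folds), function(f) {
    tr <- folds != f
    m <- train_centroid_model(expression_tibble(values[, tr, drop = FALSE], "log2"),
                              labels[tr], total_genes = config$total_genes,
                              q = 0, sd_floor = config$sd_floor)
    calls <- classify_samples(expression_tibble(values[, !tr, drop = FALSE], "log2"), m)
    sum(calls$subtype == labels[!tr])
  })
  structure(list(model = model, train_accuracy = train_acc,
                 cv_accuracy = sum(cv_hits) / length(labels)),
            class = "node_predictor_fit")
}

#' @export
print.node_predictor_fit <- function(x, ...) {
  cat("<node_predictor_fit>\n")
  cat(sprintf("  resubstitution accuracy: %.3f\n", x$train_accuracy))
  cat(sprintf("  cross-validated accuracy: %.3f\n", x$cv_accuracy))
  invisible(x)
}

#' @rdname train_binary_node_predictor
#' @param x A `node_predictor_fit`.
#' @param ... Unused.
#' @method glance node_predictor_fit
#' @export
glance.node_predictor_fit <- function(x, ...) {
  tibble(n_genes = length(x$model$genes),
         train_accuracy = x$train_accuracy, cv_accuracy = x$cv_accuracy)
}
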