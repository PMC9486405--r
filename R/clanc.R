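# Balanced ClaNC-style training machinery: per-class t-like statistics,
# balanced high/low gene selection with round-robin claiming, and
# median-centred centroid coefficients with call-strength sample exclusion.

label_classes <- function(labels) {
  if (is.factor(labels)) return(levels(labels))
  u <- unique(labels)
  if (all(u %in% hnscc_subtypes)) return(intersect(hnscc_subtypes, u))
  if (setequal(u, c("N0", "N+"))) return(c("N0", "N+"))
  sort(u)
}

check_labels <- function(expr, labels) {
  values <- as_expression_matrix(expr)
  if (is.data.frame(labels)) {
    if (!all(c("sample_id") %in% names(labels))) {
      abort("`labels` data frame must have a `sample_id` column.")
    }
    lab_col <- setdiff(names(labels), "sample_id")[1]
    v <- labels[[lab_col]][match(colnames(values), labels$sample_id)]
    if (anyNA(v)) abort("Every sample column needs a label.")
    labels <- v
  }
  if (length(labels) != ncol(values)) {
    abort("`labels` must supply one label per sample column.")
  }
  list(values = values, labels = as.character(labels))
}

#' Per-class ClaNC t-statistics
#'
#' For each gene g and class k computes
#' `t_kg = (mean_kg - mean_g) / (m_k * s_g)` where `mean_kg` is the class
#' mean, `mean_g` the overall mean, `s_g` the pooled within-class standard
#' deviation (floored at `sd_floor` so the statistic is always finite) and
#' `m_k = sqrt(1/n_k - 1/n)`. The sign of `t_kg` matches the sign of the
#' class-mean deviation, so positive values mark genes elevated in class k.
#'
#' @param expr Log2-scale expression tibble.
#' @param labels Per-sample class labels: either a vector aligned with the
#'   sample columns or a tibble with `sample_id` plus a label column.
#' @param sd_floor Lower bound on the pooled standard deviation
#'   (default 0.05 log2 units).
#' @return Tibble (class `"clanc_stats"`) with columns `gene`, `class`,
#'   `statistic`, in gene-major order; the class order is kept as an
#'   attribute `classes`.
#' @export
clanc_statistics <- function(expr, labels, sd_floor = 0.05) {
  prep <- check_labels(expr, labels)
  values <- prep$values
  labels <- prep$labels
  classes <- label_classes(labels)
  if (length(classes) < 2) abort("Need at least 2 classes.")
  n_k <- table(factor(labels, levels = classes))
  if (any(n_k < 2)) {
    abort(paste0("Every class needs >= 2 samples; too small: ",
                 paste(names(n_k)[n_k < 2], collapse = ", ")))
  }
  n <- ncol(values)
  overall_mean <- rowMeans(values)
  # pooled within-class sd, floored
  ss <- Reduce(`+`, lapply(classes, function(k) {
    sub <- values[, labels == k, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }))
  s_g <- pmax(sqrt(ss / (n - length(classes))), sd_floor)

  stats <- lapply(classes, function(k) {
    m_k <- sqrt(1 / n_k[[k]] - 1 / n)
    class_mean <- rowMeans(values[, labels == k, drop = FALSE])
    tibble(gene = rownames(values), class = k,
           statistic = unname((class_mean - overall_mean) / (m_k * s_g)))
  })
  out <- dplyr::bind_rows(stats) |> arrange(.data$gene)
  attr(out, "classes") <- classes
  class(out) <- c("clanc_stats", class(out))
  out
}

#' Balanced gene selection from ClaNC statistics
#'
#' Gives each class `total_genes / K` genes, half `"high"` (largest
#' statistic) and half `"low"` (most negative), with each gene claimed by at
#' most one class. Claiming proceeds in round-robin over ranks — every class
#' claims its rank-1 high and low gene, then rank 2, and so on — skipping
#' genes already claimed, so no class order dominates contested genes. Ties
#' in the statistic are broken by gene-identifier lexical order for
#' determinism.
#'
#' @param stats A `clanc_stats` tibble from [clanc_statistics()].
#' @param total_genes Total model size; must be divisible by `2 * K`.
#' @return Tibble with `gene`, `class` (owner), `direction`
#'   (`"high"`/`"low"`), one row per selected gene.
#' @export
select_balanced_genes <- function(stats, total_genes) {
  classes <- attr(stats, "classes")
  k <- length(classes)
  if (total_genes %% (2 * k) != 0) {
    abort(paste0("`total_genes` must be divisible by 2K = ", 2 * k, "."))
  }
  per_dir <- total_genes / (2 * k)

  ranked <- lapply(classes, function(cl) {
    sub <- stats |> filter(.data$class == cl)
    list(
      high = sub$gene[order(-sub$statistic, sub$gene)],
      low = sub$gene[order(sub$statistic, sub$gene)]
    )
  })
  names(ranked) <- classes

  claimed <- character(0)
  picks <- list()
  claim_next <- function(pool) {
    avail <- setdiff(pool, claimed)
    if (length(avail) == 0) abort("Candidate gene pool exhausted during selection.")
    avail[1]
  }
  for (r in seq_len(per_dir)) {
    for (cl in classes) {
      g <- claim_next(ranked[[cl]]$high)
      claimed <- c(claimed, g)
      picks[[length(picks) + 1]] <- tibble(gene = g, class = cl, direction = "high")
    }
    for (cl in classes) {
      g <- claim_next(ranked[[cl]]$low)
      claimed <- c(claimed, g)
      picks[[length(picks) + 1]] <- tibble(gene = g, class = cl, direction = "low")
    }
  }
  dplyr::bind_rows(picks)
}

#' Compute centroid coefficients with call-strength exclusion
#'
#' For each class, the `floor(q * n_k)` samples with the lowest call
#' strength are excluded from coefficient computation (with `q = 0.2`, a
#' class of 50 loses exactly 10). Each selected gene is then centred by its
#' overall median across all retained samples, and the coefficient for
#' class k is the within-class median of the centred values. The centring
#' constants are stored in the model so new samples need no re-centring.
#'
#' @param expr Log2-scale expression tibble.
#' @param labels Per-sample class labels (vector or tibble, as in
#'   [clanc_statistics()]).
#' @param selection Gene selection tibble (`gene`, `class`, `direction`)
#'   from [select_balanced_genes()].
#' @param strengths Optional per-sample call strengths (vector aligned with
#'   samples, or tibble with `sample_id` and `call_strength`); required when
#'   `q > 0`.
#' @param q Exclusion fraction in \[0, 1) (default 0.2).
#' @param classes Optional explicit class order; defaults to the order
#'   inferred from the labels.
#' @return A `centroid_model`.
#' @export
compute_centroids <- function(expr, labels, selection, strengths = NULL,
                              q = 0.2, classes = NULL) {
  if (q < 0 || q >= 1) abort("`q` must lie in [0, 1).")
  prep <- check_labels(expr, labels)
  values <- prep$values
  labels <- prep$labels
  classes <- classes %||% label_classes(labels)
  if (!all(selection$class %in% classes)) {
    abort("Selection references classes absent from the labels.")
  }

  if (q > 0) {
    if (is.null(strengths)) abort("`strengths` is required when `q > 0`.")
    if (is.data.frame(strengths)) {
      strengths <- strengths$call_strength[match(colnames(values),
                                                 strengths$sample_id)]
    }
    if (length(strengths) != ncol(values) || anyNA(strengths)) {
      abort("`strengths` must supply one value per sample.")
    }
  }

  keep <- rep(TRUE, ncol(values))
  if (q > 0) {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_excl <- floor(q * length(idx))
      if (n_excl >= length(idx)) {
        abort(paste0("Exclusion would empty class ", cl, "."))
      }
      if (n_excl > 0) {
        drop <- idx[order(strengths[idx])][seq_len(n_excl)]
        keep[drop] <- FALSE
      }
    }
  }
  retained <- values[, keep, drop = FALSE]
  lab_ret <- labels[keep]
  if (any(!classes %in% lab_ret)) {
    abort("A class has no retained samples.")
  }

  sel_genes <- selection$gene
  missing <- setdiff(sel_genes, rownames(retained))
  if (length(missing) > 0) {
    abort(paste0("Selected gene(s) absent from the matrix: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  sub <- retained[sel_genes, , drop = FALSE]
  overall_median <- apply(sub, 1, median)
  centred <- sub - overall_median
  coef <- vapply(classes, function(cl) {
    apply(centred[, lab_ret == cl, drop = FALSE], 1, median)
  }, numeric(length(sel_genes)))
  coef <- matrix(coef, nrow = length(sel_genes),
                 dimnames = list(sel_genes, classes))

  model <- new_centroid_model(
    subtype_names = classes, genes = sel_genes, coefficients = coef,
    gene_assignment = selection$class, gene_direction = selection$direction,
    gene_overall_median = unname(overall_median)
  )
  attr(model, "retained_samples") <- colnames(retained)
  attr(model, "excluded_samples") <- colnames(values)[!keep]
  model
}

#' Train a centroid model from labelled expression data
#'
#' Convenience wrapper chaining [clanc_statistics()],
#' [select_balanced_genes()] and [compute_centroids()]: the full balanced
#' training pipeline on one labelled matrix.
#'
#' @inheritParams compute_centroids
#' @param total_genes Model size (divisible by 2K).
#' @param sd_floor Passed to [clanc_statistics()].
#' @return A `centroid_model`.
#' @export
train_centroid_model <- function(expr, labels, total_genes, strengths = NULL,
                                 q = 0, sd_floor = 0.05) {
  stats <- clanc_statistics(expr, labels, sd_floor = sd_floor)
  selection <- select_balanced_genes(stats, total_genes)
  compute_centroids(expr, labels, selection, strengths = strengths, q = q,
                    classes = attr(stats, "classes"))
}
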