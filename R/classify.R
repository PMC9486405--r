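#' Pearson correlation distance
#'
#' The classifier's distance between a sample profile and a centroid:
#' `1 - r`, where `r` is the Pearson correlation coefficient, so the range
#' is \[0, 2\]. If either vector has zero variance the correlation is
#' undefined; the distance is then reported as 1 (no information) and the
#' result carries a `zero_variance` attribute instead of failing.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Scalar distance in \[0, 2\].
#' @examples
#' pearson_distance(c(1, 2, 3), c(1, 3, 2)) # 0.5
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Vectors must have length >= 3.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(1, zero_variance = TRUE))
  }
  1 - cor(x, y)
}

#' Silhouette-style call strength
#'
#' Confidence of a nearest-centroid call: `(b - a) / max(a, b)`, where `a`
#' is the distance to the assigned centroid and `b` the smallest distance to
#' any other centroid. Ranges over \[-1, 1\]; values near 1 indicate a
#' confident call. This is the centroid form of the silhouette (computed
#' against centroids, not pairwise between samples), so it is well defined
#' for a single sample at a time.
#'
#' @param distances Named numeric vector of per-subtype distances.
#' @param assigned Label of the assigned subtype; must attain the minimum.
#' @return Scalar in \[-1, 1\]; 0 (with a `degenerate` attribute) when both
#'   `a` and `b` are 0.
#' @examples
#' call_strength(c(basal = 0.2, mesenchymal = 0.6), "basal") # 2/3
#' @export
call_strength <- function(distances, assigned) {
  if (length(distances) < 2) abort("Need distances to at least 2 subtypes.")
  if (!assigned %in% names(distances)) abort("`assigned` not among distance names.")
  a <- distances[[assigned]]
  b <- min(distances[setdiff(names(distances), assigned)])
  if (a > min(distances) + 1e-12) {
    abort("`assigned` must attain the minimum distance.")
  }
  if (a == 0 && b == 0) return(structure(0, degenerate = TRUE))
  (b - a) / max(a, b)
}

#' Construct a centroid model
#'
#' A fitted nearest-centroid classifier: per-subtype centroid vectors over an
#' ordered gene list, plus the bookkeeping that makes the model balanced and
#' reproducible — each gene is owned by exactly one subtype with a direction
#' (`"high"`: up in that subtype, `"low"`: down), every subtype owns equally
#' many high and low genes, and each gene stores the overall median used to
#' centre it during training.
#'
#' @param subtype_names Ordered class labels (K >= 2).
#' @param genes Ordered gene identifiers.
#' @param coefficients Genes x subtypes numeric matrix (log2 units,
#'   median-centred).
#' @param gene_assignment Character vector (per gene): owning subtype.
#' @param gene_direction Character vector (per gene): `"high"` or `"low"`.
#' @param gene_overall_median Numeric vector (per gene): centring constant.
#' @return Object of class `"centroid_model"`.
#' @export
new_centroid_model <- function(subtype_names, genes, coefficients,
                               gene_assignment, gene_direction,
                               gene_overall_median) {
  model <- structure(
    list(subtype_names = subtype_names, genes = genes,
         coefficients = coefficients, gene_assignment = gene_assignment,
         gene_direction = gene_direction,
         gene_overall_median = gene_overall_median),
    class = "centroid_model"
  )
  validate_centroid_model(model)
  model
}

validate_centroid_model <- function(model) {
  stopifnot(inherits(model, "centroid_model"))
  k <- length(model$subtype_names)
  g <- length(model$genes)
  if (k < 2) abort("A centroid model needs at least 2 subtypes.")
  if (anyDuplicated(model$genes)) abort("Duplicate genes in model.")
  if (!all(dim(model$coefficients) == c(g, k))) {
    abort("`coefficients` must be genes x subtypes.")
  }
  if (length(model$gene_assignment) != g || length(model$gene_direction) != g ||
      length(model$gene_overall_median) != g) {
    abort("Per-gene fields must match the gene list length.")
  }
  if (!all(model$gene_assignment %in% model$subtype_names)) {
    abort("Every gene must be assigned to a model subtype.")
  }
  if (!all(model$gene_direction %in% c("high", "low"))) {
    abort("Gene directions must be \"high\" or \"low\".")
  }
  for (st in model$subtype_names) {
    dirs <- model$gene_direction[model$gene_assignment == st]
    if (sum(dirs == "high") != sum(dirs == "low")) {
      abort(paste0("Subtype ", st, " has unequal high/low gene counts."))
    }
  }
  invisible(model)
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("<centroid_model>\n")
  cat("  subtypes:", paste(x$subtype_names, collapse = ", "), "\n")
  cat("  genes:", length(x$genes), "(",
      paste(vapply(x$subtype_names, function(st)
        sum(x$gene_assignment == st), integer(1)), collapse = "/"),
      "per subtype )\n")
  invisible(x)
}

#' Tidy a centroid model into one row per gene
#'
#' @param x A `centroid_model`.
#' @param ... Unused.
#' @return Tibble with `gene`, `subtype` (owner), `direction`,
#'   `overall_median` and one centroid-coefficient column per subtype.
#' @method tidy centroid_model
#' @export
tidy.centroid_model <- function(x, ...) {
  coef_tbl <- as_tibble(x$coefficients, .name_repair = "minimal")
  dplyr::bind_cols(
    tibble(gene = x$genes, subtype = x$gene_assignment,
           direction = x$gene_direction,
           overall_median = x$gene_overall_median),
    coef_tbl
  )
}

#' One-row summary of a centroid model
#'
#' @param x A `centroid_model`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_subtypes`, `genes_per_subtype`,
#'   `balanced` (equal high/low per subtype).
#' @method glance centroid_model
#' @export
glance.centroid_model <- function(x, ...) {
  per <- vapply(x$subtype_names, function(st) sum(x$gene_assignment == st),
                integer(1))
  tibble(n_genes = length(x$genes), n_subtypes = length(x$subtype_names),
         genes_per_subtype = paste(per, collapse = "/"),
         balanced = TRUE)
}

#' Classify samples by nearest centroid
#'
#' Assigns each sample to the subtype whose centroid is closest in Pearson
#' correlation distance (`1 - r`), computed over the intersection of the
#' model's genes with the matrix (at least `min_present_fraction` of the
#' model genes must be present). Exact ties go to the subtype listed first in
#' the model's `subtype_names` and are flagged; samples with zero variance
#' over the model genes get distance 1 to every centroid and are flagged
#' rather than dropped. Classification is invariant to any per-sample affine
#' rescaling `a * x + b` with `a > 0`.
#'
#' @param expr Log2-scale expression tibble.
#' @param model A `centroid_model`.
#' @param min_present_fraction Minimum fraction of model genes that must be
#'   present in `expr` (default 0.8).
#' @return Tibble with one row per sample: `sample_id`, `subtype`,
#'   `call_strength`, one `dist_<subtype>` column per class, and logical
#'   flags `tie` and `zero_variance`.
#' @examples
#' sim <- simulate_expression(sim_config(n_samples = 40, seed = 2))
#' model <- train_centroid_model(sim$expression, sim$labels, total_genes = 16)
#' head(classify_samples(sim$expression, model))
#' @export
classify_samples <- function(expr, model, min_present_fraction = 0.8) {
  validate_centroid_model(model)
  aligned <- align_genes(expr, model$genes, min_present_fraction)
  values <- as_expression_matrix(aligned)
  centroids <- model$coefficients[match(rownames(values), model$genes), ,
                                  drop = FALSE]
  k <- length(model$subtype_names)

  rows <- lapply(seq_len(ncol(values)), function(j) {
    x <- values[, j]
    zv <- sd(x) == 0
    d <- vapply(seq_len(k), function(i) {
      if (zv || sd(centroids[, i]) == 0) 1 else 1 - cor(x, centroids[, i])
    }, numeric(1))
    names(d) <- model$subtype_names
    best <- which(d == min(d))
    tie <- length(best) > 1
    assigned <- model$subtype_names[best[1]]
    s <- as.numeric(call_strength(d, assigned))
    out <- tibble(sample_id = colnames(values)[j], subtype = assigned,
                  call_strength = s, tie = tie, zero_variance = zv)
    dplyr::bind_cols(out, as_tibble(as.list(setNames(d, paste0("dist_", names(d))))))
  })
  calls <- dplyr::bind_rows(rows)
  n_flag <- sum(calls$zero_variance)
  if (n_flag > 0) {
    warn(paste0(n_flag, " sample(s) had zero variance over the model genes; ",
                "their distances are uninformative (all 1)."))
  }
  calls
}

#' Serialise / deserialise a centroid model as TSV
#'
#' The layout is one row per gene with the subtype coefficient columns,
#' owning subtype, direction and overall median, preceded by `#`-prefixed
#' metadata lines recording the subtype order. Round-trips losslessly.
#'
#' @param model A `centroid_model`.
#' @param path File path.
#' @return `write_centroid_model()` returns `path` invisibly;
#'   `read_centroid_model()` returns a `centroid_model`.
#' @export
write_centroid_model <- function(model, path) {
  validate_centroid_model(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# centroid_model subtypes=",
                    paste(model$subtype_names, collapse = ",")), con)
  df <- data.frame(gene = model$genes, model$coefficients,
                   assignment = model$gene_assignment,
                   direction = model$gene_direction,
                   overall_median = model$gene_overall_median,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# centroid_model subtypes=", header)) {
    abort("Not a centroid model file (missing metadata header).")
  }
  subtypes <- strsplit(sub("^# centroid_model subtypes=", "", header), ",")[[1]]
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  coef <- as.matrix(df[, subtypes, drop = FALSE])
  rownames(coef) <- df$gene
  new_centroid_model(
    subtype_names = subtypes, genes = df$gene, coefficients = coef,
    gene_assignment = df$assignment, gene_direction = df$direction,
    gene_overall_median = df$overall_median
  )
}
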