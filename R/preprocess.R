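# Expression matrices travel as "gene tibbles": a `gene` identifier column
# followed by one numeric column per sample. A `scale_tag` attribute
# ("raw", "normalized" or "log2") records where the values sit in the
# normalise -> log2 pipeline.

#' Build an expression tibble from a genes-by-samples matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param scale One of `"raw"`, `"normalized"`, `"log2"`.
#' @return Tibble with a `gene` column then one column per sample, carrying
#'   a `scale_tag` attribute.
#' @export
expression_tibble <- function(values, scale = "log2") {
  scale <- match.arg(scale, c("raw", "normalized", "log2"))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort("Gene and sample identifiers must be unique.")
  }
  out <- dplyr::bind_cols(tibble(gene = rownames(values)),
                          as_tibble(values, .name_repair = "minimal"))
  attr(out, "scale_tag") <- scale
  out
}

#' Convert an expression tibble back to a matrix
#'
#' @param expr Expression tibble (a `gene` column plus sample columns).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
as_expression_matrix <- function(expr) {
  if (!"gene" %in% names(expr)) abort("`expr` must have a `gene` column.")
  if (anyDuplicated(expr$gene)) abort("Duplicate gene identifiers.")
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  if (!is.numeric(m)) abort("Sample columns must be numeric.")
  rownames(m) <- expr$gene
  m
}

expr_scale <- function(expr) attr(expr, "scale_tag") %||% "raw"

set_expr_scale <- function(expr, scale) {
  attr(expr, "scale_tag") <- scale
  expr
}

#' Upper-quartile normalisation
#'
#' Scales each sample so that the 75th percentile of its *positive* values
#' equals `target`. The quantile is computed with linear interpolation
#' between order statistics (R's default type-7 rule). The operation is
#' invariant to per-sample rescaling: multiplying a column by any positive
#' constant leaves the normalised output unchanged.
#'
#' @param expr Expression tibble on the raw abundance scale.
#' @param target Positive scalar the 75th percentile is mapped to
#'   (default 1000).
#' @return Normalised expression tibble (`scale_tag` = `"normalized"`).
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
#' upper_quartile_normalize(expression_tibble(m, "raw"))
#' @export
upper_quartile_normalize <- function(expr, target = 1000) {
  if (expr_scale(expr) != "raw") {
    abort("`expr` must be on the raw scale (scale_tag = \"raw\").")
  }
  if (target <= 0) abort("`target` must be strictly positive.")
  values <- as_expression_matrix(expr)
  if (any(values < 0)) abort("Raw expression values must be non-negative.")
  uq <- apply(values, 2, function(col) {
    pos <- col[col > 0]
    if (length(pos) == 0) return(NA_real_)
    quantile(pos, 0.75, type = 7, names = FALSE)
  })
  if (anyNA(uq)) {
    abort(paste0("All-zero sample(s): ",
                 paste(colnames(values)[is.na(uq)], collapse = ", ")))
  }
  scaled <- sweep(values, 2, uq, "/") * target
  expression_tibble(scaled, scale = "normalized")
}

#' Log2 transform with pseudocount
#'
#' Applies `v -> log2(v + pseudocount)` to every value. With the default
#' pseudocount of 1, zeros map to zero and the transform is strictly
#' monotone and invertible.
#'
#' @param expr Expression tibble on a raw or normalised scale.
#' @param pseudocount Offset added before taking logs (default 1).
#' @return Log2-scale expression tibble (`scale_tag` = `"log2"`).
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  if (expr_scale(expr) == "log2") abort("`expr` is already log2-transformed.")
  values <- as_expression_matrix(expr)
  if (any(values < 0)) abort("Expression values must be non-negative.")
  if (any(values + pseudocount <= 0)) abort("`pseudocount` too small: non-positive argument to log2.")
  expression_tibble(log2(values + pseudocount), scale = "log2")
}

#' Restrict an expression matrix to a classifier gene list
#'
#' Returns the matrix restricted to `gene_list`, in `gene_list` order. Genes
#' absent from the matrix are dropped and reported via an attribute (and a
#' message); if the fraction present falls below `min_present_fraction` the
#' call errors, naming the missing genes. Gene symbols are matched verbatim
#' and case-sensitively; no imputation is performed — correlation distance
#' tolerates modest gene loss, whereas imputing would invent signal.
#'
#' @param expr Expression tibble.
#' @param gene_list Character vector of gene identifiers, in the desired
#'   output order.
#' @param min_present_fraction Minimum fraction of `gene_list` that must be
#'   present (default 0.8).
#' @return Expression tibble restricted to the present genes, in list order,
#'   with attribute `missing_genes`.
#' @export
align_genes <- function(expr, gene_list, min_present_fraction = 0.8) {
  if (length(gene_list) == 0) abort("`gene_list` must be non-empty.")
  present <- gene_list[gene_list %in% expr$gene]
  missing <- setdiff(gene_list, present)
  frac <- length(present) / length(gene_list)
  if (frac < min_present_fraction) {
    abort(paste0(
      "Only ", round(100 * frac), "% of the requested genes are present ",
      "(floor ", round(100 * min_present_fraction), "%). Missing: ",
      paste(head(missing, 20), collapse = ", "),
      if (length(missing) > 20) ", ..." else ""
    ))
  }
  if (length(missing) > 0) {
    inform(paste0(length(missing), " gene(s) absent from the matrix were dropped."))
  }
  out <- expr[match(present, expr$gene), , drop = FALSE]
  out <- set_expr_scale(out, expr_scale(expr))
  attr(out, "missing_genes") <- missing
  out
}

#' Read / write a gene-by-sample expression TSV
#'
#' The layout is a header row of sample identifiers and a first column of
#' gene identifiers. Gzip-compressed files are accepted transparently on
#' read.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @param scale Scale tag to attach on read (default `"raw"`).
#' @return `read_expression_tsv()` returns an expression tibble;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, scale = "raw") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "gene"
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  expression_tibble(m, scale = scale)
}

#' @rdname read_expression_tsv
#' @param expr Expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  m <- as_expression_matrix(expr)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
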