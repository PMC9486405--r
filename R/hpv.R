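#' Call HPV status from per-type read counts
#'
#' A tumor is designated HPV-positive when its RNA-seq read count for HPV
#' type 16, 18, 33 or 35 strictly exceeds the threshold (default 1,000
#' counts), the criterion for ongoing viral replication. The default rule
#' thresholds each type separately (`rule = "any"`); `rule = "sum"` instead
#' compares the total count across the four types, for cohorts where
#' co-infection should accumulate.
#'
#' @param counts Tibble with `sample_id` and integer columns `HPV16`,
#'   `HPV18`, `HPV33`, `HPV35` (missing type columns are treated as 0).
#' @param threshold Count threshold tau (default 1000); positivity requires
#'   a count strictly greater than tau.
#' @param rule `"any"` (default): positive iff any single type exceeds tau;
#'   `"sum"`: positive iff the summed count exceeds tau.
#' @return Tibble with `sample_id`, `hpv` (`"positive"`/`"negative"`) and
#'   `max_count`.
#' @examples
#' call_hpv_status(tibble::tibble(sample_id = "s1", HPV16 = 1500,
#'                                HPV18 = 0, HPV33 = 0, HPV35 = 0))
#' @export
call_hpv_status <- function(counts, threshold = 1000, rule = c("any", "sum")) {
  rule <- match.arg(rule)
  if (!"sample_id" %in% names(counts)) abort("`counts` needs a `sample_id` column.")
  for (ty in hpv_types) {
    if (!ty %in% names(counts)) counts[[ty]] <- 0L
  }
  m <- as.matrix(counts[, hpv_types])
  if (any(m < 0)) abort("Read counts must be non-negative.")
  if (any(m != floor(m))) abort("Read counts must be integers.")
  score <- if (rule == "any") apply(m, 1, max) else rowSums(m)
  tibble(sample_id = counts$sample_id,
         hpv = ifelse(score > threshold, "positive", "negative"),
         max_count = apply(m, 1, max))
}

#' Read / write HPV count and status tables
#'
#' @param path TSV path with `sample_id` plus the four type columns.
#' @return `read_hpv_counts()` returns a tibble.
#' @export
read_hpv_counts <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' @rdname read_hpv_counts
#' @param calls Tibble from [call_hpv_status()].
#' @export
write_hpv_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
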