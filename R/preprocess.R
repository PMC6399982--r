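# Expression filtering and QC applied before network construction.
# The canonical order is: maximum-expression filter, sex-stratified
# prevalence filter, then missing-value / zero-variance QC.

#' Remove genes whose maximum expression is below a threshold
#'
#' A gene is retained iff its maximum over all samples is at or above
#' `threshold` (i.e. removed when `max < threshold`, strict).
#'
#' @param x genes x samples numeric matrix.
#' @param threshold log2-scale cutoff; default 5.
#' @return the filtered matrix, gene order preserved. Warns (does not
#'   error) if no gene survives.
#' @export
filter_by_max_expression <- function(x, threshold = 5) {
  check_expression(x)
  if (nrow(x) == 0) stop("x has no genes")
  gene_max <- apply(x, 1, max, na.rm = TRUE)
  keep <- gene_max >= threshold
  if (!any(keep)) warning("no genes pass the maximum-expression filter")
  x[keep, , drop = FALSE]
}

#' Remove genes low-expressed in most samples of either sex
#'
#' For each sex separately (samples pooled across diagnosis groups), the
#' proportion of samples with expression below `level` is computed; the gene
#' is removed when that proportion strictly exceeds `fraction` in either sex
#' (`rule = "either"`, the default) or in both sexes (`rule = "both"`).
#' Stratifying by sex prevents an uneven male/female balance from biasing
#' which genes survive.
#'
#' @param x genes x samples numeric matrix.
#' @param samples sample table with `sample_id` and `sex` columns.
#' @param level expression cutoff, default 3.
#' @param fraction prevalence cutoff, default 0.5 (strict: exactly half is
#'   retained).
#' @param rule `"either"` or `"both"`; see Details.
#' @return the filtered matrix, gene order preserved.
#' @export
filter_by_sex_prevalence <- function(x, samples, level = 3, fraction = 0.5,
                                     rule = c("either", "both")) {
  check_expression(x)
  check_samples(samples, x)
  rule <- match.arg(rule)
  samples <- samples[match(colnames(x), samples$sample_id), ]
  exceeds <- vapply(c("M", "F"), function(sx) {
    cols <- samples$sex == sx
    if (!any(cols))
      stop("sex stratum has no samples: ", sx)
    rowMeans(x[, cols, drop = FALSE] < level, na.rm = TRUE) > fraction
  }, logical(nrow(x)))
  exceeds <- matrix(exceeds, nrow = nrow(x))
  remove <- if (rule == "either") rowSums(exceeds) > 0 else
    rowSums(exceeds) == 2
  if (all(remove)) warning("no genes pass the sex-prevalence filter")
  x[!remove, , drop = FALSE]
}

#' Remove genes with missing values or zero variance
#'
#' Mirrors the usual pre-network QC: a gene with any missing cell, or with
#' zero variance across samples, is dropped (not imputed).
#'
#' @param x genes x samples numeric matrix.
#' @return list with `expression` (filtered matrix) and `report`, a list
#'   holding `removed_missing`, `removed_zero_variance` (gene ids) and
#'   `n_zero_variance_removed`.
#' @export
good_samples_genes <- function(x) {
  check_expression(x)
  has_na <- rowSums(is.na(x)) > 0
  v <- rep(NA_real_, nrow(x))
  v[!has_na] <- apply(x[!has_na, , drop = FALSE], 1, stats::var)
  zero_var <- !has_na & v == 0
  keep <- !has_na & !zero_var
  if (!any(keep)) warning("no genes pass QC")
  list(expression = x[keep, , drop = FALSE],
       report = list(removed_missing = rownames(x)[has_na],
                     removed_zero_variance = rownames(x)[zero_var],
                     n_zero_variance_removed = sum(zero_var)))
}

#' Full expression filtering stage
#'
#' Applies, in order: the maximum-expression filter, the sex-stratified
#' prevalence filter, and missing-value/zero-variance QC, and assembles a
#' filter report. Each filter is idempotent, so the composition is a
#' projection onto the analyzable gene set.
#'
#' @inheritParams filter_by_sex_prevalence
#' @param max_threshold cutoff for [filter_by_max_expression()].
#' @param level,fraction,rule passed to [filter_by_sex_prevalence()].
#' @return list with `expression` (post-QC matrix) and `report`, a
#'   `filter_report` list: `n_input_genes`, `n_after_max_filter`,
#'   `n_after_prevalence_filter`, `n_after_qc`, `n_zero_variance_removed`
#'   and per-stage `removed` gene-id lists.
#' @export
preprocess_expression <- function(x, samples, max_threshold = 5, level = 3,
                                  fraction = 0.5, rule = c("either", "both")) {
  rule <- match.arg(rule)
  n0 <- nrow(x)
  x1 <- filter_by_max_expression(x, max_threshold)
  x2 <- filter_by_sex_prevalence(x1, samples, level, fraction, rule)
  qc <- good_samples_genes(x2)
  report <- structure(list(
    n_input_genes = n0,
    n_after_max_filter = nrow(x1),
    n_after_prevalence_filter = nrow(x2),
    n_after_qc = nrow(qc$expression),
    n_zero_variance_removed = qc$report$n_zero_variance_removed,
    removed = list(
      max_filter = setdiff(rownames(x), rownames(x1)),
      prevalence_filter = setdiff(rownames(x1), rownames(x2)),
      missing = qc$report$removed_missing,
      zero_variance = qc$report$removed_zero_variance
    )
  ), class = "filter_report")
  list(expression = qc$expression, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Expression filter report\n")
  cat(sprintf("  input genes:              %d\n", x$n_input_genes))
  cat(sprintf("  after max-expression:     %d\n", x$n_after_max_filter))
  cat(sprintf("  after sex prevalence:     %d\n", x$n_after_prevalence_filter))
  cat(sprintf("  after missing/zero-var QC:%d (%d zero-variance)\n",
              x$n_after_qc, x$n_zero_variance_removed))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    stage = c("input", "max_filter", "prevalence_filter", "qc"),
    n_genes = c(report$n_input_genes, report$n_after_max_filter,
                report$n_after_prevalence_filter, report$n_after_qc),
    n_removed = c(0L,
                  report$n_input_genes - report$n_after_max_filter,
                  report$n_after_max_filter - report$n_after_prevalence_filter,
                  report$n_after_prevalence_filter - report$n_after_qc)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
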