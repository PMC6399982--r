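# Module-trait association: correlate each module eigengene with a sample
# trait and flag significant modules.

#' Associate module eigengenes with a sample trait
#'
#' Each eigengene is Pearson-correlated with the trait; diagnosis is coded
#' CTRL = 0, ICH = 1, other traits must be numeric sample-table columns.
#' The p-value is the Student-t test of the correlation on `n - 2` degrees
#' of freedom — for a binary trait this is algebraically the two-sample
#' equal-variance t-test on the eigengene. No multiple-testing correction
#' is applied by default (modules are selected at nominal p), but
#' Benjamini-Hochberg adjustment is available.
#'
#' @param eigengenes an `eigengene_matrix` from [module_eigengenes()], or a
#'   modules x samples matrix.
#' @param samples sample table; rows matched to eigengene columns by
#'   `sample_id`.
#' @param trait trait name: `"diagnosis"` or a numeric column such as
#'   `"time_since_event"` or `"age"`.
#' @param alpha significance level for the flag; default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: module, trait, correlation, p_value, significant.
#' @export
module_trait_association <- function(eigengenes, samples, trait = "diagnosis",
                                     alpha = 0.05,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  E <- if (inherits(eigengenes, "eigengene_matrix"))
    eigengenes$eigengenes else eigengenes
  if (ncol(E) < 4) stop("need at least 4 samples")
  check_samples(samples)
  samples <- samples[match(colnames(E), samples$sample_id), ]
  if (anyNA(samples$sample_id))
    stop("sample table does not cover all eigengene samples")
  y <- if (trait == "diagnosis") {
    as.numeric(samples$diagnosis == "ICH")
  } else {
    v <- samples[[trait]]
    if (is.null(v)) stop("unknown trait: ", trait)
    if (!is.numeric(v)) stop("trait must be diagnosis or numeric: ", trait)
    v
  }
  if (stats::var(y) == 0) stop("trait is constant: ", trait)
  n <- ncol(E)
  r <- as.numeric(stats::cor(t(E), y))
  # Student-t p on n - 2 df; clamp away from |r| = 1 overflow
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p_use <- if (adjust == "BH") bh_fdr(p) else p
  data.frame(module = rownames(E), trait = trait, correlation = r,
             p_value = p, significant = p_use < alpha,
             stringsAsFactors = FALSE)
}

#' Modules significant for a trait
#'
#' Convenience wrapper returning the module labels with `p < alpha`.
#' @inheritParams module_trait_association
#' @return character vector of module labels.
#' @export
significant_modules <- function(eigengenes, samples, trait = "diagnosis",
                                alpha = 0.05) {
  res <- module_trait_association(eigengenes, samples, trait, alpha)
  res$module[res$significant]
}
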