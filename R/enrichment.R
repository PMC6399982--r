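# Hypergeometric over-representation: module vs cell-type signature sets,
# and DEG-list vs external DEG-list overlap.

#' Hypergeometric overlap of two gene lists
#'
#' Tests over-representation of the overlap between two gene lists inside a
#' finite universe. Members outside the universe are dropped (with a
#' message when any are). The upper-tail probability `P(X >= q)` for
#' `X ~ Hypergeometric(N, nA, nB)` is computed by exact tail summation in
#' log space, so p-values far below double underflow of individual terms
#' are still exact; the test is symmetric in A and B.
#'
#' @param a,b character vectors of gene ids.
#' @param universe character vector, the finite gene universe.
#' @return list of class `overlap_result`: `n_universe`, `n_a`, `n_b`,
#'   `overlap` (q), `expected` (`nA * nB / N`), `p_upper`, and
#'   `intersection` (the overlapping ids, sorted).
#' @export
hypergeometric_overlap <- function(a, b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  a0 <- unique(a); b0 <- unique(b)
  a <- intersect(a0, universe)
  b <- intersect(b0, universe)
  dropped <- (length(a0) - length(a)) + (length(b0) - length(b))
  if (dropped > 0)
    message(dropped, " gene(s) outside the universe were dropped")
  N <- length(universe)
  nA <- length(a); nB <- length(b)
  inter <- sort(intersect(a, b))
  q <- length(inter)
  structure(list(n_universe = N, n_a = nA, n_b = nB, overlap = q,
                 expected = nA * nB / N,
                 p_upper = hyper_upper_tail(q, N, nA, nB),
                 intersection = inter),
            class = "overlap_result")
}

# P(X >= q) for X ~ Hypergeometric(population N, successes nA, draws nB),
# by log-space summation of exact binomial-coefficient terms.
hyper_upper_tail <- function(q, N, nA, nB) {
  hi <- min(nA, nB)
  lo <- max(0L, nA + nB - N)  # smallest attainable overlap
  if (q <= lo) return(1)
  if (q > hi) return(0)
  ks <- q:hi
  logs <- lchoose(nA, ks) + lchoose(N - nA, nB - ks) - lchoose(N, nB)
  min(1, exp(logsumexp(logs)))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap %d of (%d x %d) in universe %d; expected %.2f; p = %.3g\n",
    x$overlap, x$n_a, x$n_b, x$n_universe, x$expected, x$p_upper))
  invisible(x)
}

#' Cell-type enrichment of co-expression modules
#'
#' Overlaps each non-grey module's gene list with each cell-type signature
#' set by [hypergeometric_overlap()], flags significance at `alpha`, and
#' sorts by p-value.
#'
#' @param partition gene -> module label vector.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()] or the generator).
#' @param universe gene universe; must contain every module gene.
#'   Conventionally the post-filter analyzed gene set.
#' @param alpha significance level; default 0.05.
#' @return data.frame: module, gene_set, n_module, n_set, overlap,
#'   expected, p_value, significant; sorted by p_value.
#' @export
celltype_enrichment <- function(partition, gene_sets, universe,
                                alpha = 0.05) {
  genes <- names(partition)
  if (!all(genes %in% universe))
    stop("universe must contain every module gene")
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets)))
    stop("gene_sets must be a uniquely named list")
  mods <- names(module_sizes(partition))
  rows <- list()
  for (m in mods) {
    mg <- genes[partition == m]
    for (s in names(gene_sets)) {
      ov <- suppressMessages(
        hypergeometric_overlap(mg, gene_sets[[s]], universe))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, gene_set = s, n_module = ov$n_a, n_set = ov$n_b,
        overlap = ov$overlap, expected = ov$expected, p_value = ov$p_upper,
        significant = ov$p_upper < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$module, out$gene_set), , drop = FALSE]
}

#' Overlap between two differential-expression gene lists
#'
#' Cross-study DEG comparison (e.g. blood-derived vs brain-derived DEG
#' lists): identical to [hypergeometric_overlap()], returning the
#' intersection gene list for reporting.
#'
#' @inheritParams hypergeometric_overlap
#' @param deg_a,deg_b character vectors of differentially expressed gene
#'   ids.
#' @return an `overlap_result` (see [hypergeometric_overlap()]).
#' @export
deg_overlap <- function(deg_a, deg_b, universe) {
  hypergeometric_overlap(deg_a, deg_b, universe)
}
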