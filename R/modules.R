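# Module detection on the gene dendrogram, module eigengenes,
# intramodular connectivity, and hub identification.

#' Tree-based dynamic cut of a gene dendrogram
#'
#' A single cut height defines the candidate branches; each branch with at
#' least `min_module_size` leaves is accepted as a module, and the
#' remaining leaves are labeled `"grey"` (unassigned). With
#' `deep_split = TRUE` each accepted branch is further examined: it is
#' re-cut within its own height range, and replaced by its sub-branches
#' when at least two of them independently reach `min_module_size`. The
#' default `deep_split = FALSE` performs no fine splitting. Modules are
#' labeled by descending size with the conventional color vocabulary
#' (turquoise, blue, brown, ...).
#'
#' The default `cut_method = "gap"` places the cut adaptively in the
#' widest gap of the upper half of the merge-height distribution,
#' preferring (in decreasing gap width) the first candidate that yields at
#' least two full-sized branches. This makes branch detection invariant to
#' the strong height compression that high soft-thresholding powers induce
#' on topological-overlap dissimilarities. `cut_method = "static"` cuts at
#' `cut_height_fraction * max(height)`. Neither is a bit-exact replica of
#' the reference tree-cut algorithm; the contract is planted-module
#' recovery (see the vignette).
#'
#' @param tree an `hclust` object over genes (e.g. [build_dendrogram()]).
#' @param min_module_size minimum leaves per accepted module; default 100.
#' @param deep_split logical; default FALSE.
#' @param cut_height_fraction cut height as a fraction of the maximum
#'   merge height (used by `cut_method = "static"`); default 0.99.
#' @param cut_method `"gap"` (default) or `"static"`.
#' @return named character vector mapping gene id to module label
#'   (`"grey"` = unassigned), class `module_partition`, with attributes
#'   `min_module_size`, `cut_height` and `module_sizes` (named,
#'   descending, grey last).
#' @export
dynamic_tree_cut <- function(tree, min_module_size = 100, deep_split = FALSE,
                             cut_height_fraction = 0.99,
                             cut_method = c("gap", "static")) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (min_module_size < 1) stop("min_module_size must be >= 1")
  cut_method <- match.arg(cut_method)
  leaves <- tree$labels
  if (is.null(leaves)) leaves <- as.character(seq_len(length(tree$order)))
  n <- length(leaves)
  cut_h <- if (cut_method == "static" || length(tree$height) < 3)
    cut_height_fraction * max(tree$height)
  else gap_cut_height(tree, min_module_size, cut_height_fraction)
  branch <- stats::cutree(tree, h = cut_h)
  groups <- split(seq_len(n), branch)
  accepted <- list()
  for (g in groups) {
    if (length(g) < min_module_size) next
    pieces <- list(g)
    if (isTRUE(deep_split)) pieces <- split_branch(tree, g,
                                                   min_module_size,
                                                   cut_height_fraction)
    accepted <- c(accepted, pieces)
  }
  labels <- rep("grey", n)
  if (length(accepted)) {
    ord <- order(vapply(accepted, length, integer(1)), decreasing = TRUE)
    for (k in seq_along(ord))
      labels[accepted[[ord[k]]]] <- module_label(k)
  }
  names(labels) <- leaves
  sizes <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  sizes <- c(sizes, grey = sum(labels == "grey"))
  structure(labels, class = "module_partition",
            min_module_size = min_module_size,
            cut_height = cut_h,
            module_sizes = sizes)
}

# Adaptive cut-height placement: candidate cuts are the midpoints of the
# widest gaps among merge heights in the upper half of the height
# distribution. Candidates are tried in decreasing gap width; the first
# yielding >= 2 branches of min_module_size wins, then the first yielding
# >= 1, then the widest gap. Falls back to the static fraction cut for
# degenerate height distributions.
gap_cut_height <- function(tree, min_module_size, cut_height_fraction,
                           n_candidates = 10L) {
  h <- sort(tree$height)
  top <- h[h >= stats::median(h)]
  gaps <- diff(top)
  if (length(gaps) == 0 || max(gaps) == 0)
    return(cut_height_fraction * max(h))
  ord <- order(gaps, decreasing = TRUE)[seq_len(min(n_candidates,
                                                    length(gaps)))]
  cands <- (top[ord] + top[ord + 1]) / 2
  n_acc <- vapply(cands, function(ch) {
    cl <- stats::cutree(tree, h = ch)
    sum(table(cl) >= min_module_size)
  }, integer(1))
  if (any(n_acc >= 2)) return(cands[which(n_acc >= 2)[1]])
  if (any(n_acc >= 1)) return(cands[which(n_acc >= 1)[1]])
  cands[1]
}

# Re-cut one accepted branch within its own height range; keep the
# sub-branches only when >= 2 of them are full-sized modules on their own,
# otherwise the branch stays whole.
split_branch <- function(tree, idx, min_module_size, cut_height_fraction) {
  if (length(idx) < 2 * min_module_size) return(list(idx))
  d <- stats::cophenetic(tree)
  sub <- stats::hclust(stats::as.dist(as.matrix(d)[idx, idx]),
                       method = "average")
  h <- if (length(sub$height) < 3) cut_height_fraction * max(sub$height)
  else gap_cut_height(sub, min_module_size, cut_height_fraction)
  sublab <- stats::cutree(sub, h = h)
  parts <- split(idx, sublab)
  big <- parts[vapply(parts, length, integer(1)) >= min_module_size]
  if (length(big) < 2) return(list(idx))
  unname(big)
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- attr(x, "module_sizes")
  cat("Module partition:", sum(names(sizes) != "grey"), "modules over",
      length(x), "genes\n")
  print(sizes)
  invisible(x)
}

#' Module sizes of a partition
#' @param partition a `module_partition` (or any gene -> label vector).
#' @param include_grey include the unassigned count; default FALSE.
#' @return named integer vector, descending.
#' @export
module_sizes <- function(partition, include_grey = FALSE) {
  tab <- table(partition)
  if (!include_grey) tab <- tab[names(tab) != "grey"]
  sort(tab, decreasing = TRUE)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member genes after per-gene standardization, computed over samples,
#' unit-normalized, and oriented so that its mean correlation with the
#' member genes is nonnegative. The proportion of (standardized) expression
#' variance it explains is reported per module.
#'
#' @param x genes x samples expression matrix.
#' @param partition gene -> module label vector; `"grey"` is skipped.
#' @return list of class `eigengene_matrix`: `eigengenes` (modules x
#'   samples matrix, rows unit-norm) and `variance_explained` (named
#'   vector in (0,1\]).
#' @export
module_eigengenes <- function(x, partition) {
  check_expression(x)
  genes <- intersect(names(partition), rownames(x))
  if (!length(genes)) stop("partition and expression matrix share no genes")
  mods <- setdiff(unique(partition[genes]), "grey")
  mods <- names(sort(module_sizes(partition[genes]), decreasing = TRUE))
  E <- matrix(NA_real_, length(mods), ncol(x),
              dimnames = list(mods, colnames(x)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- genes[partition[genes] == m]
    xm <- x[members, , drop = FALSE]
    xm <- t(scale(t(xm)))  # per-gene mean 0, SD 1
    if (length(members) == 1) {
      warning("module ", m, " has a single gene; eigengene equals the ",
              "standardized gene")
      e <- as.numeric(xm)
      e <- e / sqrt(sum(e^2))
      E[m, ] <- e
      ve[m] <- 1
      next
    }
    sv <- svd(xm, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(e, t(xm))) < 0) e <- -e
    E[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = E, variance_explained = ve),
            class = "eigengene_matrix")
}

#' @export
print.eigengene_matrix <- function(x, ...) {
  cat("Eigengenes for", nrow(x$eigengenes), "modules over",
      ncol(x$eigengenes), "samples\n")
  cat("variance explained:\n")
  print(round(x$variance_explained, 3))
  invisible(x)
}

#' Whole-network and intramodular connectivity
#'
#' `kTotal_i` sums gene i's adjacencies to all other genes; `kIN_i` sums
#' only within gene i's own module; `kOut = kTotal - kIN`. Grey (unassigned)
#' genes get `kIN = 0`.
#'
#' @param A adjacency matrix.
#' @param partition gene -> module label vector covering A's genes.
#' @return data.frame: gene_id, module, kTotal, kIN, kOut, hub (all FALSE
#'   until [identify_hubs()]).
#' @export
intramodular_connectivity <- function(A, partition) {
  genes <- rownames(A)
  if (!all(genes %in% names(partition)))
    stop("partition must cover all genes in A")
  lab <- partition[genes]
  A0 <- A
  diag(A0) <- 0
  kTotal <- rowSums(A0)
  same <- outer(lab, lab, "==") & lab[row(A0)] != "grey"
  kIN <- rowSums(A0 * same)
  kIN[lab == "grey"] <- 0
  data.frame(gene_id = genes, module = unname(lab),
             kTotal = unname(kTotal), kIN = unname(kIN),
             kOut = unname(kTotal - kIN), hub = FALSE,
             stringsAsFactors = FALSE)
}

#' Flag intramodular hub genes
#'
#' Within each non-grey module, the `ceiling(fraction * module size)` genes
#' with highest intramodular connectivity (kIN) are flagged as hubs. Ties at
#' the boundary are broken by lexicographic gene id so the hub set is
#' deterministic and invariant to input order. Grey genes are never hubs.
#'
#' @param connectivity a connectivity table from
#'   [intramodular_connectivity()].
#' @param fraction hub fraction in (0, 1\]; default 0.05 (top 5%).
#' @return the table with `hub` set.
#' @export
identify_hubs <- function(connectivity, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- connectivity
  k$hub <- FALSE
  for (m in setdiff(unique(k$module), "grey")) {
    rows <- which(k$module == m)
    n_hub <- ceiling(fraction * length(rows))
    ord <- rows[order(-k$kIN[rows], k$gene_id[rows])]
    k$hub[ord[seq_len(n_hub)]] <- TRUE
  }
  k
}
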