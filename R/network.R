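# Weighted co-expression network construction: Pearson correlation,
# scale-free soft-threshold selection, unsigned adjacency, topological
# overlap, and the gene dendrogram.

#' Pearson correlation matrix between genes
#'
#' @param x genes x samples numeric matrix with at least 3 samples and no
#'   zero-variance genes.
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  check_expression(x)
  if (ncol(x) < 3) stop("need at least 3 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
  C <- stats::cor(t(x))
  diag(C) <- 1
  C
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor_ij| ^ power`, with unit diagonal. The unsigned transform
#' treats strong negative co-expression the same as strong positive.
#'
#' @param C symmetric correlation matrix.
#' @param power soft-thresholding exponent beta (>= 1); default 8.
#' @return adjacency matrix with attribute `"power"`.
#' @export
adjacency_matrix <- function(C, power = 8) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be a square matrix")
  if (power < 1) stop("power must be >= 1")
  A <- abs(C)^power
  diag(A) <- 1
  attr(A, "power") <- power
  A
}

#' Scale-free topology scan over candidate soft-thresholding powers
#'
#' For each candidate power beta the unsigned adjacency `|cor|^beta` is
#' formed and connectivities `k_i = sum_{j != i} a_ij` computed. The
#' connectivity distribution is summarized in `nbins` equal-width bins
#' (empty bins dropped) and `log10(frequency)` regressed on `log10(mean k
#' per bin)`; the signed scale-free fit is `-sign(slope) * R^2`, so a
#' decreasing (scale-free-like) degree distribution scores positively. The
#' chosen power is the lowest beta whose signed fit reaches `r2_threshold`;
#' if none does, the argmax is returned with a warning.
#'
#' Bins are equal-width on the raw connectivity scale by default, matching
#' the field's reference scale-free fit index; `bin_scale = "log10k"`
#' selects equal-width binning of `log10(k)` instead (see the vignette for
#' why the raw scale is the default).
#'
#' @param C symmetric correlation matrix.
#' @param powers candidate integer powers, default 1:20.
#' @param r2_threshold signed-R^2 acceptance threshold, default 0.8.
#' @param nbins number of connectivity histogram bins, default 10.
#' @param bin_scale `"k"` (default) or `"log10k"`.
#' @return object of class `power_selection`: data.frame `scan` with
#'   columns power, r_squared (signed), slope, mean_connectivity,
#'   median_connectivity, max_connectivity; plus `chosen_power` and
#'   `r2_threshold`.
#' @export
soft_threshold_scan <- function(C, powers = 1:20, r2_threshold = 0.8,
                                nbins = 10, bin_scale = c("k", "log10k")) {
  bin_scale <- match.arg(bin_scale)
  if (length(powers) == 0 || any(powers < 1))
    stop("powers must be a nonempty vector of positive values")
  powers <- sort(unique(as.integer(powers)))
  scan <- data.frame(power = powers, r_squared = NA_real_, slope = NA_real_,
                     mean_connectivity = NA_real_,
                     median_connectivity = NA_real_,
                     max_connectivity = NA_real_)
  absC <- abs(C)
  diag(absC) <- 0
  for (i in seq_along(powers)) {
    k <- rowSums(absC^powers[i])
    fit <- scale_free_fit(k, nbins, bin_scale)
    scan$r_squared[i] <- fit$signed_r2
    scan$slope[i] <- fit$slope
    scan$mean_connectivity[i] <- mean(k)
    scan$median_connectivity[i] <- stats::median(k)
    scan$max_connectivity[i] <- max(k)
  }
  chosen <- select_power(scan$power, scan$r_squared, r2_threshold)
  structure(list(scan = scan, chosen_power = chosen,
                 r2_threshold = r2_threshold),
            class = "power_selection")
}

# Lowest power whose signed R^2 reaches the threshold; otherwise the argmax
# with a warning. Exposed separately so the selection rule is testable on
# precomputed scan tables.
select_power <- function(powers, r_squared, r2_threshold = 0.8) {
  pass <- which(r_squared >= r2_threshold)
  if (length(pass)) return(powers[pass[1]])
  warning("no candidate power reaches signed R^2 >= ", r2_threshold,
          "; returning the best-fitting power")
  powers[which.max(r_squared)]
}

# Signed scale-free fit of a connectivity vector.
scale_free_fit <- function(k, nbins = 10, bin_scale = "k") {
  k <- k[k > 0]
  if (length(unique(k)) < 2)
    stop("degenerate connectivity histogram: all connectivities identical")
  kb <- if (bin_scale == "log10k") log10(k) else k
  breaks <- seq(min(kb), max(kb), length.out = nbins + 1)
  breaks[1] <- breaks[1] - 1e-8 * max(1, abs(breaks[1]))  # include the min
  bin <- cut(kb, breaks = breaks, labels = FALSE)
  freq <- tabulate(bin, nbins)
  keep <- freq > 0
  if (sum(keep) < 2)
    stop("degenerate connectivity histogram: fewer than 2 occupied bins")
  mean_k <- vapply(which(keep), function(b) mean(k[bin == b]), numeric(1))
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' @export
print.power_selection <- function(x, ...) {
  cat("Soft-threshold scan (signed scale-free R^2, threshold ",
      x$r2_threshold, ")\n", sep = "")
  print(x$scan[, c("power", "r_squared", "mean_connectivity")],
        row.names = FALSE, digits = 3)
  cat("chosen power:", x$chosen_power, "\n")
  invisible(x)
}

#' Topological overlap matrix
#'
#' For `i != j`:
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `w_ii = 1`. Two genes overlap strongly when they are directly connected
#' and share neighbors.
#'
#' @param A adjacency matrix (entries in \[0,1\], unit diagonal).
#' @return TOM matrix, same dimnames, unit diagonal.
#' @export
topological_overlap <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  A0 <- A
  diag(A0) <- 0
  L <- A0 %*% A0              # with zero diagonal, u = i,j terms vanish
  k <- rowSums(A0)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - A0
  W <- (L + A0) / denom
  if (any(denom == 0)) {
    warning("zero TOM denominator; setting affected overlaps to 0")
    W[denom == 0] <- 0
  }
  diag(W) <- 1
  dimnames(W) <- dimnames(A)
  W
}

#' Average-linkage gene dendrogram
#'
#' Clusters genes on a dissimilarity matrix, conventionally `1 - TOM`.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return an `hclust` object (merge heights nondecreasing by construction
#'   of average linkage).
#' @export
build_dendrogram <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-10) stop("D must be symmetric")
  if (any(abs(diag(D)) > 1e-10)) stop("D must have zero diagonal")
  stats::hclust(stats::as.dist(D), method = "average")
}
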