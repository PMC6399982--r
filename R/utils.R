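# Internal helpers shared across the pipeline.

# Module label vocabulary, in assignment order (largest module first).
# "grey" is reserved for unassigned genes and never appears here.
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen", "skyblue3",
  "plum1", "orangered4", "mediumpurple3", "lightsteelblue1", "lightcyan1",
  "ivory", "floralwhite", "darkorange2", "brown4", "bisque4", "darkslateblue",
  "plum2", "thistle2"
)

#' Module label for the k-th largest module
#'
#' Returns the conventional color label used for module `k` in descending
#' size order; falls back to `"moduleK"` past the color vocabulary.
#' @param k positive integer rank (1 = largest module).
#' @return character label.
#' @keywords internal
module_label <- function(k) {
  ifelse(k <= length(.module_colors), .module_colors[k], paste0("module", k))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of planted modules. 1 = identical partitions,
#' ~0 = agreement expected by chance.
#'
#' @param a,b vectors of equal length giving the two labelings.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  if (length(a) < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# log(sum(exp(x))) without overflow/underflow; used for exact
# hypergeometric tail sums.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Format a numeric column for TSV output. Expression matrices keep 12
# significant digits (round-trip stable to ~1e-9 relative); result tables
# use 6.
fmt_num <- function(x, digits = 6L) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- ""
  out
}

# Check an object looks like a genes x samples expression matrix.
check_expression <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric genes x samples matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(arg, " must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  invisible(x)
}

# Check a sample table against an expression matrix.
check_samples <- function(samples, x = NULL) {
  need <- c("sample_id", "diagnosis", "sex")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(samples$diagnosis %in% c("ICH", "CTRL")))
    stop("diagnosis must be ICH or CTRL")
  if (!all(samples$sex %in% c("M", "F")))
    stop("sex must be M or F")
  if (!is.null(x)) {
    if (!setequal(samples$sample_id, colnames(x)) ||
        anyDuplicated(samples$sample_id))
      stop("sample table rows must match expression matrix columns 1:1")
  }
  invisible(samples)
}
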