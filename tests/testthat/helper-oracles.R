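# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own computational paths.

# Topological overlap by explicit triple loop.
tom_oracle <- function(A) {
  n <- nrow(A)
  W <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l_ij <- 0
    for (u in seq_len(n)) if (u != i && u != j) l_ij <- l_ij + A[i, u] * A[u, j]
    denom <- min(k[i], k[j]) + 1 - A[i, j]
    W[i, j] <- if (denom == 0) 0 else (l_ij + A[i, j]) / denom
  }
  dimnames(W) <- dimnames(A)
  W
}

# Intramodular connectivity by explicit double loop.
kin_oracle <- function(A, labels) {
  n <- nrow(A)
  out <- data.frame(gene_id = rownames(A), kTotal = 0, kIN = 0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out$kTotal[i] <- out$kTotal[i] + A[i, j]
    if (labels[i] != "grey" && labels[i] == labels[j])
      out$kIN[i] <- out$kIN[i] + A[i, j]
  }
  out
}

# Pearson correlation via the direct two-pass covariance/SD formula.
cor_oracle <- function(x) {
  n <- nrow(x)
  C <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- x[i, ] - mean(x[i, ])
    xj <- x[j, ] - mean(x[j, ])
    C[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  C
}

# Hypergeometric upper tail P(|A ∩ B| >= q) by exhaustive enumeration of
# every possible draw B of size nb from a universe of size n, with A fixed.
hyper_oracle <- function(q, n, na, nb) {
  draws <- utils::combn(n, nb)
  mean(colSums(draws <= na) >= q)
}

# Benjamini-Hochberg step-up by its textbook definition, O(m^2).
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  sapply(seq_len(m), function(i) {
    min(1, min((m / r[p >= p[i]]) * p[p >= p[i]]))
  })
}

# Random symmetric adjacency in [0,1] with unit diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  A
}

# Background-only null worlds (no modules). `iid = TRUE` additionally
# switches off every covariate effect: the setting where KS/binomial
# calibration bounds for the unadjusted t-test are exact (see vignette).
# With `iid = FALSE` covariate effects stay on and calibration is assessed
# through the model that adjusts for them.
null_sim <- function(seed, n_genes = 1200L, iid = FALSE) {
  extra <- if (iid)
    list(batch_sd = 0, sex_effect_sd = 0, age_slope_sd = 0,
         time_slope_sd = 0) else list()
  args <- c(list(n_genes = n_genes, module_sizes = integer(0),
                 dx_effect_sizes = numeric(0),
                 low_expression_fraction = 0, seed = seed), extra)
  generate_dataset(do.call(sim_config, args))
}

# Shared small fixture: a quick, well-separated simulated dataset.
small_sim <- function(seed = 1, ...) {
  defaults <- list(n_genes = 500L, module_sizes = c(120L, 100L),
                   dx_effect_sizes = c(1, 0), n_background_genes = NULL,
                   low_expression_fraction = 0.1, seed = seed)
  cf <- utils::modifyList(defaults, list(...))
  generate_dataset(do.call(sim_config, cf))
}

# Planted truth labels aligned to a partition, NA -> "none".
truth_labels <- function(sim, partition) {
  tm <- sim$truth$true_module[match(names(partition), sim$truth$gene_id)]
  ifelse(is.na(tm), "none", tm)
}
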