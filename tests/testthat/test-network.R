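# Network construction: correlation, soft-threshold selection, adjacency,
# topological overlap, dendrogram. Brute-force oracles pin the math.

test_that("correlation matches the direct two-pass formula", {
  set.seed(4)
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("S", 1:4)))
  expect_equal(unname(correlation_matrix(x)), cor_oracle(x),
               tolerance = 1e-12)
  # duplicated gene -> correlation 1; negated gene -> -1
  x2 <- rbind(x, dup = x[1, ], neg = -x[1, ])
  C <- correlation_matrix(x2)
  expect_equal(C["g1", "dup"], 1)
  expect_equal(C["g1", "neg"], -1)
  # zero-variance gene errors with its name
  x3 <- rbind(x, flat = rep(2, 4))
  expect_error(correlation_matrix(x3), "flat")
  expect_error(correlation_matrix(x[, 1:2]), "3 samples")
})

test_that("adjacency is the unsigned power transform", {
  C <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3)
  A <- adjacency_matrix(C, 8)
  expect_equal(A[1, 2], 0.00390625)
  expect_equal(A[1, 3], 1)      # |c| = 1 regardless of sign
  expect_equal(adjacency_matrix(C, 1)[1, 2], 0.5)  # beta = 1 is |c|
  expect_true(all(diag(A) == 1))
  expect_error(adjacency_matrix(C, 0.5), "power")
})

test_that("power selection takes the lowest beta passing the threshold", {
  # constructed scan mirroring the conventional beta = 8 choice
  powers <- 6:9
  r2 <- c(0.55, 0.78, 0.86, 0.88)
  expect_equal(select_power(powers, r2, 0.8), 8)
  # no beta passes -> argmax with a warning
  expect_warning(got <- select_power(powers, c(0.1, 0.3, 0.7, 0.5), 0.8),
                 "best-fitting")
  expect_equal(got, 8)
  expect_error(soft_threshold_scan(diag(3), powers = numeric(0)), "powers")
})

test_that("soft-threshold scan is deterministic and well-formed", {
  d <- small_sim(seed = 6)
  pq <- preprocess_expression(d$expression, d$samples)
  C <- correlation_matrix(pq$expression)
  ps1 <- suppressWarnings(soft_threshold_scan(C, powers = 1:12))
  ps2 <- suppressWarnings(soft_threshold_scan(C, powers = 1:12))
  expect_identical(ps1$scan, ps2$scan)
  expect_identical(ps1$chosen_power, ps2$chosen_power)
  expect_true(all(diff(ps1$scan$mean_connectivity) < 0))
  # degenerate all-equal connectivities error
  expect_error(scale_free_fit(rep(2, 10)), "degenerate")
})

test_that("TOM matches the triple-loop oracle", {
  # worked 3-gene case: all off-diagonal a = 0.5
  A <- matrix(0.5, 3, 3); diag(A) <- 1
  dimnames(A) <- list(paste0("g", 1:3), paste0("g", 1:3))
  W <- topological_overlap(A)
  expect_equal(W[1, 2], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  # zero adjacency -> zero overlap
  A0 <- diag(3)
  dimnames(A0) <- dimnames(A)
  expect_equal(unname(topological_overlap(A0)), diag(3))
  # random matrices up to 12 genes agree with the oracle to 1e-12
  for (n in c(4, 6, 9, 12)) {
    An <- random_adjacency(n, seed = n)
    expect_equal(topological_overlap(An), tom_oracle(An),
                 tolerance = 1e-12)
  }
})

test_that("adjacency and TOM stay symmetric in [0,1] on random inputs", {
  set.seed(99)
  for (rep in 1:5) {
    x <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(paste0("g", 1:30), paste0("S", 1:10)))
    C <- correlation_matrix(x)
    A <- adjacency_matrix(C, sample(1:12, 1))
    W <- topological_overlap(A)
    for (M in list(A, W)) {
      expect_equal(M, t(M), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1 + 1e-12))
    }
  }
})

test_that("dendrogram construction behaves as average linkage", {
  # duplicate genes merge first at height 0
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 0, 9),
             d = c(9, 0, 2, 1))
  colnames(x) <- paste0("S", 1:4)
  D <- 1 - abs(correlation_matrix(x))
  diag(D) <- 0
  tr <- build_dendrogram(D)
  first <- sort(tr$labels[-tr$merge[1, ]])
  expect_identical(first, c("a", "b"))
  expect_equal(min(tr$height), 0)
  expect_true(all(diff(tr$height) >= -1e-12))
  # block dissimilarity: first two merges stay within blocks
  Db <- matrix(0.9, 4, 4); Db[1:2, 1:2] <- 0.1; Db[3:4, 3:4] <- 0.1
  diag(Db) <- 0
  dimnames(Db) <- list(letters[1:4], letters[1:4])
  trb <- build_dendrogram(Db)
  m1 <- sort(-trb$merge[1, ]); m2 <- sort(-trb$merge[2, ])
  expect_true(identical(m1, c(1L, 2L)) || identical(m1, c(3L, 4L)))
  expect_true(identical(m2, c(1L, 2L)) || identical(m2, c(3L, 4L)))
  # malformed input
  Dn <- Db; Dn[1, 2] <- 0.5
  expect_error(build_dendrogram(Dn), "symmetric")
  Dd <- Db; diag(Dd) <- 1
  expect_error(build_dendrogram(Dd), "diagonal")
})
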