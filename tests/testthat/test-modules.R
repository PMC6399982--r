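# Module detection, eigengenes, connectivity and hub flags.

# expression matrix with planted orthogonal modules and optional noise genes
planted_modules <- function(sizes, n_noise = 0, n_samples = 66,
                            loading = c(0.6, 0.9), noise_sd = 0.5,
                            seed = 1) {
  set.seed(seed)
  n <- sum(sizes) + n_noise
  u <- matrix(rnorm(length(sizes) * n_samples), length(sizes))
  x <- matrix(rnorm(n * n_samples, sd = noise_sd), n, n_samples)
  row0 <- 0
  for (m in seq_along(sizes)) {
    lo <- runif(sizes[m], loading[1], loading[2])
    x[row0 + seq_len(sizes[m]), ] <-
      x[row0 + seq_len(sizes[m]), ] + lo %o% u[m, ]
    row0 <- row0 + sizes[m]
  }
  dimnames(x) <- list(sprintf("g%04d", seq_len(n)),
                      sprintf("S%03d", seq_len(n_samples)))
  list(x = x, u = u,
       truth = rep(c(seq_along(sizes), 0), c(sizes, n_noise)))
}

cluster_tree <- function(x, power = 8) {
  A <- adjacency_matrix(correlation_matrix(x), power)
  W <- topological_overlap(A)
  D <- 1 - W
  diag(D) <- 0
  list(tree = build_dendrogram(D), A = A, W = W)
}

test_that("two planted orthogonal modules are recovered exactly", {
  pm <- planted_modules(c(120, 120), seed = 2)
  part <- dynamic_tree_cut(cluster_tree(pm$x)$tree, min_module_size = 100)
  sz <- module_sizes(part)
  expect_equal(length(sz), 2)
  expect_equal(unname(as.integer(sz)), c(120, 120))
  expect_equal(sum(part == "grey"), 0)
  expect_equal(adjusted_rand_index(part, pm$truth), 1)
})

test_that("a single tight cluster is found and noise genes stay grey", {
  pm <- planted_modules(150, n_noise = 20, seed = 3)
  part <- dynamic_tree_cut(cluster_tree(pm$x)$tree, min_module_size = 100)
  expect_equal(unname(as.integer(module_sizes(part))), 150)
  expect_equal(sum(part == "grey"), 20)
  expect_true(all(part[pm$truth == 0] == "grey"))
})

test_that("min_module_size forces small inputs to grey", {
  pm <- planted_modules(c(25, 25), seed = 4)
  part <- dynamic_tree_cut(cluster_tree(pm$x)$tree, min_module_size = 100)
  expect_true(all(part == "grey"))
  expect_error(dynamic_tree_cut(cluster_tree(pm$x)$tree,
                                min_module_size = 0), "min_module_size")
})

test_that("labels follow the size-ordered color vocabulary", {
  pm <- planted_modules(c(150, 120, 110), seed = 5)
  part <- dynamic_tree_cut(cluster_tree(pm$x)$tree, min_module_size = 100)
  sz <- module_sizes(part)
  expect_identical(names(sz), c("turquoise", "blue", "brown"))
  expect_true(all(diff(as.integer(sz)) <= 0))
})

test_that("eigengenes recover the latent factor and orient positively", {
  for (seed in 1:5) {
    pm <- planted_modules(100, n_samples = 66, seed = seed)
    part <- structure(rep("turquoise", 100), names = rownames(pm$x))
    eig <- module_eigengenes(pm$x, part)
    e <- eig$eigengenes["turquoise", ]
    expect_gte(abs(cor(e, pm$u[1, ])), 0.95)
    expect_equal(sum(e^2), 1, tolerance = 1e-8)
    xm <- t(scale(t(pm$x)))
    expect_gte(mean(cor(e, t(xm))), 0)
    expect_true(eig$variance_explained["turquoise"] > 0 &&
                  eig$variance_explained["turquoise"] <= 1)
  }
})

test_that("rank-1 module gives eigengene proportional to the profile", {
  v <- sin(1:20)
  x <- rbind(a = v, b = 2 * v + 3, c = -v)  # same profile up to affine sign
  colnames(x) <- paste0("S", 1:20)
  part <- structure(rep("blue", 3), names = rownames(x))
  eig <- module_eigengenes(x, part)
  e <- eig$eigengenes["blue", ]
  expect_equal(abs(cor(e, v)), 1, tolerance = 1e-10)
  expect_equal(unname(eig$variance_explained["blue"]), 1, tolerance = 1e-10)
  # flipping every gene's sign flips nothing observable: orientation keeps
  # mean member-correlation nonnegative
  xm2 <- t(scale(t(-x)))
  eig2 <- module_eigengenes(-x, part)
  expect_gte(mean(cor(eig2$eigengenes["blue", ], t(xm2))), 0)
})

test_that("eigengene variance explained rises as noise falls", {
  med_ve <- sapply(c(1.0, 0.6, 0.3), function(ns) {
    pm <- planted_modules(c(100, 100), noise_sd = ns, seed = 7)
    part <- structure(rep(c("turquoise", "blue"), each = 100),
                      names = rownames(pm$x))
    median(module_eigengenes(pm$x, part)$variance_explained)
  })
  expect_true(all(diff(med_ve) > 0))
})

test_that("single-gene module warns and returns the standardized gene", {
  x <- rbind(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  colnames(x) <- paste0("S", 1:10)
  part <- structure(c("turquoise", "turquoise", "blue"),
                    names = rownames(x))
  expect_warning(eig <- module_eigengenes(x, part), "single gene")
  expect_equal(abs(cor(eig$eigengenes["blue", ], x["c", ])), 1,
               tolerance = 1e-10)
})

test_that("connectivity matches the double-loop oracle and its identity", {
  A <- random_adjacency(8, seed = 31)
  labels <- structure(c(rep("turquoise", 3), rep("blue", 3), "grey", "grey"),
                      names = rownames(A))
  k <- intramodular_connectivity(A, labels)
  oracle <- kin_oracle(A, labels)
  expect_equal(k$kTotal, oracle$kTotal, tolerance = 1e-12)
  expect_equal(k$kIN, oracle$kIN, tolerance = 1e-12)
  expect_equal(k$kTotal, k$kIN + k$kOut, tolerance = 1e-12)
  expect_true(all(k$kIN[k$module == "grey"] == 0))
  # 3-gene module with all pairwise a = 0.5 has kIN = 1 each
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 1
  dimnames(A3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  k3 <- intramodular_connectivity(
    A3, structure(rep("turquoise", 3), names = rownames(A3)))
  expect_equal(k3$kIN, rep(1, 3))
  # singleton module has kIN 0
  ks <- intramodular_connectivity(
    A3, structure(c("turquoise", "blue", "blue"), names = rownames(A3)))
  expect_equal(ks$kIN[1], 0)
})

test_that("hub flags follow the ceiling rule with lexicographic ties", {
  mk_conn <- function(n, kin, module = "turquoise") {
    data.frame(gene_id = sprintf("g%03d", seq_len(n)), module = module,
               kTotal = kin, kIN = kin, kOut = 0, hub = FALSE,
               stringsAsFactors = FALSE)
  }
  # 100 genes at 5% -> exactly 5 hubs, the top-5 kIN
  k <- mk_conn(100, kin = seq(100, 1))
  h <- identify_hubs(k)
  expect_equal(sum(h$hub), 5)
  expect_true(all(h$hub[1:5]))
  # 10 genes -> ceil(0.5) = 1 hub
  expect_equal(sum(identify_hubs(mk_conn(10, kin = 10:1))$hub), 1)
  # all ties -> 5 lexicographically smallest ids
  ht <- identify_hubs(mk_conn(100, kin = rep(1, 100)))
  expect_identical(ht$gene_id[ht$hub], sprintf("g%03d", 1:5))
  # grey never flagged
  kg <- mk_conn(100, kin = seq(100, 1), module = "grey")
  expect_equal(sum(identify_hubs(kg)$hub), 0)
  expect_error(identify_hubs(k, fraction = 0), "fraction")
})

test_that("hub set is invariant to gene input order", {
  A <- random_adjacency(30, seed = 77)
  labels <- structure(rep(c("turquoise", "blue", "grey"), each = 10),
                      names = rownames(A))
  h1 <- identify_hubs(intramodular_connectivity(A, labels), 0.2)
  perm <- sample(30)
  h2 <- identify_hubs(
    intramodular_connectivity(A[perm, perm], labels[perm]), 0.2)
  expect_setequal(h1$gene_id[h1$hub], h2$gene_id[h2$hub])
})
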