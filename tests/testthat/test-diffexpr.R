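# Mixed-effects differential expression, BH-FDR, fold change.

de_samples <- function(n = 66, n_batches = 6, seed = 1) {
  set.seed(seed)
  s <- data.frame(sample_id = sprintf("S%03d", 1:n),
                  diagnosis = rep(c("ICH", "CTRL"), each = n / 2),
                  sex = rep(rep(c("M", "F"), c(24, 9)), length.out = n),
                  age = round(runif(n, 40, 85)),
                  time_since_event = runif(n, 5, 120),
                  stringsAsFactors = FALSE)
  s$scan_date <- sprintf("B%02d", rep_len(seq_len(n_batches), n))
  s
}

sim_gene <- function(s, effect = 0, batch_sd = 0, resid_sd = 1) {
  b <- rnorm(length(unique(s$scan_date)), 0, batch_sd)
  names(b) <- unique(s$scan_date)
  6 + effect * (s$diagnosis == "ICH") + b[s$scan_date] +
    rnorm(nrow(s), 0, resid_sd)
}

test_that("BH step-up matches the hand-worked example and the oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)  # m = 1 identity
  set.seed(7)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-15)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-15)
    expect_true(all(adj >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("signed fold change encodes direction with magnitude >= 1", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-1), -2)
  expect_equal(signed_fold_change(0), 1)
  d <- runif(50, -3, 3)
  expect_true(all(abs(signed_fold_change(d)) >= 1))
})

test_that("single-batch balanced design reduces to the pooled t-test", {
  s <- de_samples(n = 40, n_batches = 1, seed = 3)
  set.seed(4)
  y <- sim_gene(s, effect = 0.5)
  spec <- design_spec(covariates = character(0),
                      dx_sex_interaction = FALSE)
  fit <- fit_gene_model(y, s, spec)
  expect_identical(fit$method, "lm")
  tt <- t.test(y[s$diagnosis == "ICH"], y[s$diagnosis == "CTRL"],
               var.equal = TRUE)
  expect_equal(fit$p_dx, tt$p.value, tolerance = 1e-8)
  expect_equal(fit$effect, -diff(tt$estimate)[[1]], tolerance = 1e-8)
})

test_that("degenerate responses and designs error informatively", {
  s <- de_samples(seed = 5)
  expect_error(fit_gene_model(rep(3, nrow(s)), s), "zero-variance")
  s2 <- s
  s2$age <- 2 * s2$time_since_event  # collinear
  set.seed(6)
  expect_error(
    fit_gene_model(rnorm(nrow(s2)), s2,
                   design_spec(covariates = c("age", "time_since_event"),
                               dx_sex_interaction = FALSE)),
    "collinear")
})

test_that("REML recovers a planted diagnosis effect with batch variance", {
  s <- de_samples(seed = 8)
  set.seed(9)
  fit <- fit_gene_model(sim_gene(s, effect = 1, batch_sd = 0.5), s)
  expect_identical(fit$method, "lmm")
  expect_equal(fit$effect, 1, tolerance = 0.5)  # single-gene sanity only
  expect_true(all(fit$varcomp >= 0))
  expect_named(fit$varcomp, c("batch", "residual"))
})

test_that("p_dx is invariant to adding a constant to the response", {
  s <- de_samples(seed = 10)
  set.seed(11)
  y <- sim_gene(s, effect = 0.4, batch_sd = 0.3)
  f1 <- fit_gene_model(y, s)
  f2 <- fit_gene_model(y + 100, s)
  expect_equal(f1$p_dx, f2$p_dx, tolerance = 1e-8)
  expect_equal(f1$effect, f2$effect, tolerance = 1e-8)
})

test_that("with zero batch variance the mixed p matches fixed ANCOVA", {
  s <- de_samples(seed = 12)
  set.seed(13)
  y <- sim_gene(s, effect = 0.5, batch_sd = 0)
  fm <- fit_gene_model(y, s, design_spec(random_batch = TRUE))
  fl <- fit_gene_model(y, s, design_spec(random_batch = FALSE))
  expect_equal(fm$p_dx, fl$p_dx, tolerance = 1e-4)
})

test_that("differential_expression applies the FDR and FC rule exactly", {
  s <- de_samples(seed = 14)
  set.seed(15)
  n_genes <- 60
  x <- t(sapply(seq_len(n_genes), function(i)
    sim_gene(s, effect = if (i <= 10) 1.2 else 0, batch_sd = 0.3)))
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)), s$sample_id)
  de <- differential_expression(x, s)
  expect_equal(nrow(de), n_genes)
  expect_equal(de$significant,
               de$fdr < 0.05 & abs(de$fold_change) > 1.2)
  expect_equal(de$fdr, bh_fdr(de$p_dx))
  expect_true(all(de$fdr >= de$p_dx))
  expect_equal(de$fold_change, signed_fold_change(de$delta))
  # planted strong effects dominate the significant set
  expect_gt(mean(de$significant[1:10]), 0.5)
  expect_lt(mean(de$significant[-(1:10)]), 0.2)
})

test_that("planted effects are detected with controlled false flags", {
  # 100 affected genes (effect 1.0 log2) among 1000 (scaled down from
  # 2000 to keep runtime in budget), batch SD 0.5: >= 70% of affected
  # flagged and <= 5% false flags among nulls, in >= 8 of 10 seeds. The
  # generative world here has no sex/age/time effects, so the fitted model
  # is the matching one (diagnosis + random batch intercept).
  n_seeds <- 10
  ok <- 0
  spec <- design_spec(covariates = character(0),
                      dx_sex_interaction = FALSE)
  for (seed in seq_len(n_seeds)) {
    s <- de_samples(seed = 700 + seed)
    set.seed(800 + seed)
    n_genes <- 1000
    x <- t(sapply(seq_len(n_genes), function(i)
      sim_gene(s, effect = if (i <= 100) 1.0 else 0, batch_sd = 0.5)))
    dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)), s$sample_id)
    de <- differential_expression(x, s, spec)
    power <- mean(de$significant[1:100])
    false_rate <- mean(de$significant[-(1:100)])
    ok <- ok + (power >= 0.7 && false_rate <= 0.05)
  }
  expect_gte(ok, 8)
})

test_that("per-gene fit failures are excluded from FDR with a count", {
  s <- de_samples(seed = 16)
  set.seed(17)
  x <- rbind(good1 = sim_gene(s), flat = rep(2, nrow(s)),
             good2 = sim_gene(s))
  colnames(x) <- s$sample_id
  expect_message(de <- differential_expression(x, s), "failed to fit")
  expect_equal(nrow(de), 2)
  expect_equal(attr(de, "n_failed"), 1)
})
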