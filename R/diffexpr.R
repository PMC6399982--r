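# Per-gene mixed-effects differential expression: diagnosis effect
# adjusted for sex, age, draw time and a diagnosis x sex interaction, with
# scan-date as a random intercept estimated by REML; BH-FDR across genes
# and signed fold changes from model-adjusted group means.

#' Differential-expression model specification
#'
#' Fixed effects: diagnosis (reference CTRL), sex (reference F), optional
#' diagnosis x sex interaction, plus the listed continuous covariates.
#' Scan date enters as a random intercept (REML) when `random_batch` is
#' TRUE and at least two batches are present; otherwise an ordinary
#' fixed-effects ANCOVA is fitted.
#'
#' @param covariates continuous/additional fixed-effect columns of the
#'   sample table; default `c("sex", "age", "time_since_event")`
#'   (`"sex"` is coded as a factor).
#' @param dx_sex_interaction include diagnosis:sex; default TRUE.
#' @param random_batch scan-date random intercept; default TRUE.
#' @param dx_test `"main"` (Wald test of the diagnosis main effect at the
#'   reference sex, the default) or `"joint"` (F-test of the diagnosis main
#'   effect and its sex interaction together).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(covariates = c("sex", "age", "time_since_event"),
                        dx_sex_interaction = TRUE, random_batch = TRUE,
                        dx_test = c("main", "joint")) {
  dx_test <- match.arg(dx_test)
  if (dx_sex_interaction && !"sex" %in% covariates)
    stop("dx_sex_interaction requires 'sex' among the covariates")
  structure(list(covariates = covariates,
                 dx_sex_interaction = dx_sex_interaction,
                 random_batch = random_batch, dx_test = dx_test),
            class = "design_spec")
}

# Model frame with reference-coded factors.
de_model_frame <- function(samples, spec) {
  df <- data.frame(
    diagnosis = factor(samples$diagnosis, levels = c("CTRL", "ICH")))
  for (v in spec$covariates) {
    col <- samples[[v]]
    if (is.null(col)) stop("sample table lacks covariate: ", v)
    df[[v]] <- if (v == "sex") factor(col, levels = c("F", "M")) else col
  }
  if (spec$random_batch) {
    if (is.null(samples$scan_date))
      stop("sample table lacks covariate: scan_date")
    df$scan_date <- factor(samples$scan_date)
  }
  df
}

de_fixed_formula <- function(spec, response = "y") {
  rhs <- c("diagnosis", spec$covariates,
           if (spec$dx_sex_interaction) "diagnosis:sex")
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

# Wald statistics for the diagnosis effect from fixed-effect estimates.
# The tested quantity is the marginal (least-squares-means) ICH - CTRL
# contrast, averaged equally over the sexes when the interaction is in the
# model: contrast = beta_dx + 0.5 * beta_dx:sexM. This matches the
# type-III main-effect convention of ANCOVA platforms. Residual degrees of
# freedom n - p (no Satterthwaite correction; a documented
# simplification).
dx_wald <- function(beta, V, n, spec) {
  p <- length(beta)
  df <- n - p
  i_dx <- which(names(beta) == "diagnosisICH")
  i_int <- grep("^diagnosisICH:sexM$", names(beta))
  contrast <- rep(0, p)
  contrast[i_dx] <- 1
  if (length(i_int)) contrast[i_int] <- 0.5
  est <- drop(contrast %*% beta)
  se <- sqrt(drop(t(contrast) %*% V %*% contrast))
  if (spec$dx_test == "joint" && length(i_int)) {
    idx <- c(i_dx, i_int)
    b <- beta[idx]
    Fstat <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b) /
      length(idx)
    p_dx <- stats::pf(Fstat, length(idx), df, lower.tail = FALSE)
  } else {
    p_dx <- 2 * stats::pt(-abs(est / se), df = df)
  }
  list(effect = est, se = se, p_dx = p_dx, delta_adjusted = est, df = df)
}

#' Fit the differential-expression model for one gene
#'
#' @param y numeric expression vector (log2), one value per sample.
#' @param samples sample table (diagnosis, sex, age, scan_date,
#'   time_since_event).
#' @param spec a [design_spec()].
#' @return list: `effect` (diagnosis coefficient at the reference sex,
#'   log2), `se`, `p_dx`, `delta_adjusted` (ICH - CTRL least-squares-means
#'   difference), `varcomp` (named: batch, residual), `method`
#'   (`"lmm"` or `"lm"`), `df`.
#' @export
fit_gene_model <- function(y, samples, spec = design_spec()) {
  if (length(y) != nrow(samples))
    stop("y and samples disagree in length")
  if (stats::var(y) == 0) stop("zero-variance response")
  df <- de_model_frame(samples, spec)
  df$y <- y
  X <- stats::model.matrix(de_fixed_formula(spec), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular model matrix; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  use_lmm <- spec$random_batch && nlevels(df$scan_date) >= 2
  if (use_lmm) {
    fo <- stats::update(de_fixed_formula(spec), . ~ . + (1 | scan_date))
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(fo, data = df, REML = TRUE)))
    beta <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
    vc <- as.data.frame(lme4::VarCorr(m))
    varcomp <- c(batch = vc$vcov[vc$grp == "scan_date"],
                 residual = vc$vcov[vc$grp == "Residual"])
  } else {
    m <- stats::lm(de_fixed_formula(spec), data = df)
    beta <- stats::coef(m)
    V <- stats::vcov(m)
    varcomp <- c(batch = 0, residual = summary(m)$sigma^2)
  }
  if (varcomp["residual"] <= 0) stop("zero residual variance")
  w <- dx_wald(beta, V, nrow(df), spec)
  c(w, list(varcomp = varcomp, method = if (use_lmm) "lmm" else "lm"))
}

#' Genome-wide differential expression
#'
#' Fits the model of [fit_gene_model()] to every gene (re-using the fitted
#' mixed-model structure across genes for speed), adjusts diagnosis
#' p-values by Benjamini-Hochberg across all successfully fitted genes, and
#' derives signed fold changes. A gene is called significant when
#' `fdr < fdr_threshold` and `|fold_change| > fc_threshold`.
#'
#' @param x post-QC genes x samples expression matrix (log2).
#' @param samples sample table.
#' @param spec a [design_spec()].
#' @param fdr_threshold BH-FDR cutoff; default 0.05.
#' @param fc_threshold absolute signed fold-change cutoff; default 1.2.
#' @param fc_means `"adjusted"` (least-squares group means, default) or
#'   `"raw"` (unadjusted group means).
#' @return data.frame of class `de_result`: gene_id, effect (log2),
#'   delta (log2 group-mean difference used for FC), fold_change (signed),
#'   p_dx, fdr, significant. Genes whose fit failed are excluded from the
#'   FDR and reported in attribute `"n_failed"` (with a message).
#' @export
differential_expression <- function(x, samples, spec = design_spec(),
                                    fdr_threshold = 0.05,
                                    fc_threshold = 1.2,
                                    fc_means = c("adjusted", "raw")) {
  check_expression(x)
  check_samples(samples, x)
  fc_means <- match.arg(fc_means)
  samples <- samples[match(colnames(x), samples$sample_id), ]
  df <- de_model_frame(samples, spec)
  use_lmm <- spec$random_batch && nlevels(df$scan_date) >= 2
  n <- ncol(x)

  template <- NULL
  fit_one <- function(y) {
    if (use_lmm) {
      if (is.null(template)) {
        fo <- stats::update(de_fixed_formula(spec), . ~ . + (1 | scan_date))
        d <- df
        d$y <- y
        template <<- suppressMessages(suppressWarnings(
          lme4::lmer(fo, data = d, REML = TRUE)))
        m <- template
      } else {
        m <- suppressMessages(suppressWarnings(lme4::refit(template, y)))
      }
      dx_wald(lme4::fixef(m), as.matrix(stats::vcov(m)), n, spec)
    } else {
      d <- df
      d$y <- y
      m <- stats::lm(de_fixed_formula(spec), data = d)
      dx_wald(stats::coef(m), stats::vcov(m), n, spec)
    }
  }

  is_ich <- samples$diagnosis == "ICH"
  res <- vector("list", nrow(x))
  failed <- character(0)
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    w <- tryCatch({
      if (stats::var(y) == 0) stop("zero-variance response")
      fit_one(y)
    }, error = function(e) NULL)
    if (is.null(w)) {
      failed <- c(failed, rownames(x)[i])
      next
    }
    delta <- if (fc_means == "raw")
      mean(y[is_ich]) - mean(y[!is_ich]) else w$delta_adjusted
    res[[i]] <- data.frame(gene_id = rownames(x)[i], effect = w$effect,
                           delta = delta, p_dx = w$p_dx,
                           stringsAsFactors = FALSE)
  }
  if (length(failed))
    message(length(failed), " gene(s) failed to fit and were excluded ",
            "from FDR")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no gene could be fitted")
  out$fold_change <- signed_fold_change(out$delta)
  out$fdr <- bh_fdr(out$p_dx)
  out$significant <- out$fdr < fdr_threshold &
    abs(out$fold_change) > fc_threshold
  out <- out[, c("gene_id", "effect", "delta", "fold_change", "p_dx",
                 "fdr", "significant")]
  attr(out, "n_failed") <- length(failed)
  attr(out, "thresholds") <- c(fdr = fdr_threshold, fc = fc_threshold)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order; monotone in the input ranks.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pvals[o]))
  adj[order(o)]
}

#' Signed fold change from a log2 difference
#'
#' `delta` is the ICH - CTRL difference of (adjusted) group means on the
#' log2 scale. The ratio `r = 2^delta` is reported as `r` when `r >= 1`
#' and `-1/r` otherwise, so magnitude is always >= 1 and the sign encodes
#' direction.
#'
#' @param delta numeric vector of log2 differences.
#' @return signed fold changes.
#' @export
signed_fold_change <- function(delta) {
  r <- 2^delta
  ifelse(r >= 1, r, -1 / r)
}
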