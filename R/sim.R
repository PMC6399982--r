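#' Configuration for the synthetic blood-expression generator
#'
#' Describes a case-control blood transcriptome study on the log2 scale:
#' latent-factor-driven co-expression modules, a diagnosis shift on a subset
#' of module factors, sex/age/batch/blood-draw-time covariate effects,
#' cell-type labels concentrated within modules, and a fraction of
#' low-expressed genes built to fail the expression filters.
#'
#' The default design mirrors a 66-subject study: 33 cases and 33 controls,
#' each 24 male / 9 female, with draw times spanning roughly 4-124 hours
#' after the event.
#'
#' @param n_ich,n_ctrl number of case (ICH) and control samples.
#' @param males_per_group number of male samples within each group.
#' @param n_genes total genes emitted (module members + background +
#'   low-expressed).
#' @param module_sizes integer vector of planted module sizes.
#' @param dx_effect_sizes per-module shift of the latent factor mean in ICH
#'   samples, in factor SD units; length matches `module_sizes`.
#' @param loading_range range of per-gene loadings on the module factor.
#' @param noise_sd per-observation residual SD (log2 units).
#' @param baseline_mean baseline log2 expression level.
#' @param low_expression_fraction fraction of `n_genes` constructed to fail
#'   the QC expression filters.
#' @param celltype_purity fraction of each module's genes carrying that
#'   module's cell-type label.
#' @param n_batches number of scan-date batches, assigned round-robin within
#'   each diagnosis group so batches span both groups.
#' @param batch_sd SD of per-gene random batch intercepts.
#' @param sex_effect_sd SD of per-gene additive male-vs-female effects.
#' @param age_slope_sd SD of per-gene slopes on centered age (per year).
#' @param time_slope_sd SD of per-gene slopes on centered draw time (per hour).
#' @param seed integer RNG seed; the whole dataset is a pure function of the
#'   configuration.
#' @param n_background_genes optional; defaults to
#'   `n_genes - sum(module_sizes) - round(low_expression_fraction * n_genes)`.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
sim_config <- function(n_ich = 33L, n_ctrl = 33L, males_per_group = 24L,
                       n_genes = 2000L,
                       module_sizes = c(300L, 250L, 200L, 150L, 120L),
                       dx_effect_sizes = c(1, 0.8, 0, 0, 0),
                       loading_range = c(0.4, 0.9),
                       noise_sd = 0.5,
                       baseline_mean = 6,
                       low_expression_fraction = 0.1,
                       celltype_purity = 0.6,
                       n_batches = 6L,
                       batch_sd = 0.3,
                       sex_effect_sd = 0.2,
                       age_slope_sd = 0.01,
                       time_slope_sd = 0.002,
                       seed = 1L,
                       n_background_genes = NULL) {
  chk_count <- function(v, nm, min = 0L) {
    if (length(v) != 1 || !is.finite(v) || v < min || v != round(v))
      stop("invalid configuration field: ", nm)
    as.integer(v)
  }
  n_ich <- chk_count(n_ich, "n_ich", 1L)
  n_ctrl <- chk_count(n_ctrl, "n_ctrl", 1L)
  males_per_group <- chk_count(males_per_group, "males_per_group")
  if (males_per_group > min(n_ich, n_ctrl))
    stop("invalid configuration field: males_per_group (exceeds group size)")
  n_genes <- chk_count(n_genes, "n_genes", 1L)
  n_batches <- chk_count(n_batches, "n_batches", 1L)
  module_sizes <- vapply(module_sizes, chk_count, integer(1),
                         nm = "module_sizes", min = 2L)
  if (length(dx_effect_sizes) != length(module_sizes))
    stop("invalid configuration field: dx_effect_sizes ",
         "(length must match module_sizes)")
  for (nm in c("noise_sd", "batch_sd", "sex_effect_sd", "age_slope_sd",
               "time_slope_sd")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      stop("invalid configuration field: ", nm)
  }
  for (nm in c("low_expression_fraction", "celltype_purity")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      stop("invalid configuration field: ", nm)
  }
  if (length(loading_range) != 2 || any(!is.finite(loading_range)) ||
      loading_range[1] > loading_range[2])
    stop("invalid configuration field: loading_range")
  n_low <- as.integer(round(low_expression_fraction * n_genes))
  if (is.null(n_background_genes))
    n_background_genes <- n_genes - sum(module_sizes) - n_low
  n_background_genes <- chk_count(n_background_genes, "n_background_genes")
  if (sum(module_sizes) + n_background_genes + n_low != n_genes)
    stop("invalid configuration field: n_genes (module_sizes + ",
         "n_background_genes + low-expression genes must sum to n_genes)")
  structure(list(
    n_ich = n_ich, n_ctrl = n_ctrl, males_per_group = males_per_group,
    n_genes = n_genes, module_sizes = module_sizes,
    dx_effect_sizes = as.numeric(dx_effect_sizes),
    loading_range = as.numeric(loading_range), noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    low_expression_fraction = low_expression_fraction,
    celltype_purity = celltype_purity, n_batches = n_batches,
    batch_sd = batch_sd, sex_effect_sd = sex_effect_sd,
    age_slope_sd = age_slope_sd, time_slope_sd = time_slope_sd,
    seed = as.integer(seed), n_background_genes = n_background_genes,
    n_low_genes = n_low
  ), class = "sim_config")
}

# Cell-type vocabulary cycled over modules, in order.
.celltypes <- c("neutrophil", "monocyte", "tcell", "nk", "erythroblast",
                "bcell", "megakaryocyte", "helper_tcell")

#' Generate a synthetic case-control blood expression dataset
#'
#' Simulates a genes x samples log2 expression matrix with planted
#' co-expression modules, a matching sample table, a ground-truth gene
#' table, and cell-type gene sets. Module member genes follow
#' `baseline + loading * u_m + batch + sex + age + time + noise`, where the
#' per-sample latent factor `u_m` is standard normal, shifted by the
#' module's diagnosis effect in ICH samples. Background genes carry only
#' baseline, covariates, and noise. Low-expressed genes are constructed so
#' that either their maximum is below 5 or more than half of one sex's
#' samples fall below 3, exercising both QC filters.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `coex_sim` with elements
#'   \describe{
#'     \item{expression}{numeric genes x samples matrix (log2 scale).}
#'     \item{samples}{data.frame: sample_id, diagnosis, sex, age, scan_date,
#'       time_since_event.}
#'     \item{truth}{data.frame: gene_id, role, true_module, loading,
#'       celltype_label, is_dx_affected.}
#'     \item{gene_sets}{named list of cell-type gene sets (character
#'       vectors), one per planted module, diluted with background genes.}
#'     \item{latent_factors}{modules x samples matrix of the factors `u_m`.}
#'     \item{config}{the configuration used.}
#'   }
#'   Identical configurations (including seed) give bit-identical output.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_ich + cf$n_ctrl
  n_mod <- length(cf$module_sizes)

  ## ---- samples ----
  grp_sex <- function(ng) c(rep("M", cf$males_per_group),
                            rep("F", ng - cf$males_per_group))
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    diagnosis = c(rep("ICH", cf$n_ich), rep("CTRL", cf$n_ctrl)),
    sex = c(grp_sex(cf$n_ich), grp_sex(cf$n_ctrl)),
    stringsAsFactors = FALSE
  )
  samples$age <- pmin(90, pmax(30, round(stats::rnorm(n, 62.5, 14))))
  # round-robin batches within each group so every batch spans both groups
  batch_of <- function(ng) ((seq_len(ng) - 1L) %% cf$n_batches) + 1L
  samples$scan_date <- sprintf("B%02d", c(batch_of(cf$n_ich),
                                          batch_of(cf$n_ctrl)))
  # controls receive a draw-time too (modeling choice; see the vignette)
  samples$time_since_event <- round(stats::runif(n, 4.2, 124.3), 1)

  is_ich <- samples$diagnosis == "ICH"
  is_male <- samples$sex == "M"
  age_c <- samples$age - mean(samples$age)
  time_c <- samples$time_since_event - mean(samples$time_since_event)
  batch_idx <- as.integer(sub("^B", "", samples$scan_date))

  ## ---- latent factors ----
  u <- matrix(stats::rnorm(n_mod * n), n_mod, n)
  dimnames(u) <- list(if (n_mod) paste0("factor", seq_len(n_mod)),
                      samples$sample_id)
  if (n_mod) u <- u + cf$dx_effect_sizes %o% as.numeric(is_ich)

  ## ---- gene bookkeeping ----
  gene_id <- sprintf("G%05d", seq_len(cf$n_genes))
  role <- c(rep("module-member", sum(cf$module_sizes)),
            rep("background", cf$n_background_genes),
            rep("low-expressed", cf$n_low_genes))
  true_module <- rep(NA_character_, cf$n_genes)
  true_module[seq_len(sum(cf$module_sizes))] <-
    rep(module_label(seq_len(n_mod)), cf$module_sizes)
  loading <- rep(NA_real_, cf$n_genes)
  celltype <- rep(NA_character_, cf$n_genes)
  is_dx <- rep(FALSE, cf$n_genes)

  expr <- matrix(NA_real_, cf$n_genes, n,
                 dimnames = list(gene_id, samples$sample_id))

  # covariate effects drawn per gene; shared machinery for module +
  # background genes
  covariate_part <- function(ng) {
    b <- matrix(stats::rnorm(ng * cf$n_batches, 0, cf$batch_sd),
                ng, cf$n_batches)
    sexe <- stats::rnorm(ng, 0, cf$sex_effect_sd)
    agee <- stats::rnorm(ng, 0, cf$age_slope_sd)
    time <- stats::rnorm(ng, 0, cf$time_slope_sd)
    b[, batch_idx, drop = FALSE] +
      sexe %o% as.numeric(is_male) + agee %o% age_c + time %o% time_c
  }

  row0 <- 0L
  for (m in seq_len(n_mod)) {
    sz <- cf$module_sizes[m]
    rows <- row0 + seq_len(sz)
    lo <- stats::runif(sz, cf$loading_range[1], cf$loading_range[2])
    loading[rows] <- lo
    is_dx[rows] <- cf$dx_effect_sizes[m] != 0
    n_lab <- round(cf$celltype_purity * sz)
    lab <- .celltypes[((m - 1L) %% length(.celltypes)) + 1L]
    if (n_lab > 0) celltype[rows[sample.int(sz, n_lab)]] <- lab
    expr[rows, ] <- cf$baseline_mean + lo %o% u[m, ] + covariate_part(sz) +
      matrix(stats::rnorm(sz * n, 0, cf$noise_sd), sz, n)
    row0 <- row0 + sz
  }
  if (cf$n_background_genes > 0) {
    rows <- row0 + seq_len(cf$n_background_genes)
    expr[rows, ] <- cf$baseline_mean + covariate_part(length(rows)) +
      matrix(stats::rnorm(length(rows) * n, 0, cf$noise_sd), length(rows), n)
    row0 <- row0 + cf$n_background_genes
  }
  if (cf$n_low_genes > 0) {
    # first half: max expression < 5 everywhere; rest: males below 3 in
    # every sample while females sit comfortably above both thresholds
    n_maxfail <- ceiling(cf$n_low_genes / 2)
    for (i in seq_len(cf$n_low_genes)) {
      r <- row0 + i
      if (i <= n_maxfail) {
        expr[r, ] <- stats::runif(n, 1, 4.5)
      } else {
        v <- numeric(n)
        v[is_male] <- stats::runif(sum(is_male), 1, 2.9)
        v[!is_male] <- stats::runif(sum(!is_male), 5.5, 7)
        expr[r, ] <- v
      }
    }
  }

  truth <- data.frame(gene_id = gene_id, role = role,
                      true_module = true_module, loading = loading,
                      celltype_label = celltype, is_dx_affected = is_dx,
                      stringsAsFactors = FALSE)

  ## ---- cell-type gene sets ----
  bg_ids <- truth$gene_id[truth$role == "background"]
  gene_sets <- list()
  for (m in seq_len(n_mod)) {
    lab <- .celltypes[((m - 1L) %% length(.celltypes)) + 1L]
    members <- truth$gene_id[!is.na(truth$celltype_label) &
                               truth$celltype_label == lab]
    n_extra <- max(5L, round(0.25 * length(members)))
    n_extra <- min(n_extra, length(bg_ids))
    extra <- if (n_extra > 0) sample(bg_ids, n_extra) else character(0)
    gene_sets[[lab]] <- sort(unique(c(members, extra)))
  }

  structure(list(expression = expr, samples = samples, truth = truth,
                 gene_sets = gene_sets, latent_factors = u, config = cf),
            class = "coex_sim")
}

#' @export
print.coex_sim <- function(x, ...) {
  cf <- x$config
  cat("Synthetic co-expression dataset\n")
  cat(sprintf("  %d genes x %d samples (%d ICH / %d CTRL)\n",
              nrow(x$expression), ncol(x$expression), cf$n_ich, cf$n_ctrl))
  cat(sprintf("  modules: %s\n",
              paste(sprintf("%s(%d)", module_label(seq_along(cf$module_sizes)),
                            cf$module_sizes), collapse = ", ")))
  cat(sprintf("  background %d, low-expressed %d, seed %d\n",
              cf$n_background_genes, cf$n_low_genes, cf$seed))
  invisible(x)
}
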