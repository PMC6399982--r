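# End-to-end orchestration: filtering -> network -> modules -> eigengenes
# -> trait association -> hubs -> enrichment -> differential expression ->
# optional external DEG overlap, with every artifact written as TSV and a
# run log capturing all parameters.

#' Pipeline configuration
#'
#' Names either a simulation block (a [sim_config()]) or input file paths,
#' plus every analysis threshold. Defaults follow the conventional
#' case-control blood workflow: max-expression filter at 5, sex-prevalence
#' filter at 3 / 50%, soft-threshold grid 1-20 with signed R^2 >= 0.8,
#' minimum module size 100, top-5% hubs, module significance at nominal
#' p < 0.05, DE significance at FDR < 0.05 and |FC| > 1.2, edge export
#' capped at 10,000 rows.
#'
#' @param simulation a [sim_config()], or NULL when reading files.
#' @param expression_file,sample_file,gene_sets_file input paths (TSV,
#'   TSV, GMT); ignored when `simulation` is given.
#' @param external_degs optional character vector of external DEG ids for
#'   the cross-study overlap stage.
#' @param output_dir where result TSVs and the run log are written; NULL
#'   keeps everything in memory.
#' @param max_threshold,level,fraction,prevalence_rule filtering stage.
#' @param powers,r2_threshold soft-threshold scan.
#' @param min_module_size,deep_split,cut_height_fraction module detection.
#' @param dissimilarity `"tom"` (default) or `"cor"`: cluster on 1 - TOM
#'   or on 1 - |cor|^beta.
#' @param hub_fraction top fraction of kIN flagged per module.
#' @param module_alpha nominal p cutoff for module-trait significance.
#' @param fdr_threshold,fc_threshold DE significance rule.
#' @param min_edge_weight,max_edges edge export for significant modules.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, expression_file = NULL,
                            sample_file = NULL, gene_sets_file = NULL,
                            external_degs = NULL, output_dir = NULL,
                            max_threshold = 5, level = 3, fraction = 0.5,
                            prevalence_rule = "either",
                            powers = 1:20, r2_threshold = 0.8,
                            min_module_size = 100, deep_split = FALSE,
                            cut_height_fraction = 0.99,
                            dissimilarity = c("tom", "cor"),
                            hub_fraction = 0.05, module_alpha = 0.05,
                            fdr_threshold = 0.05, fc_threshold = 1.2,
                            min_edge_weight = 0.1, max_edges = 10000) {
  dissimilarity <- match.arg(dissimilarity)
  if (is.null(simulation)) {
    for (nm in c("expression_file", "sample_file")) {
      if (is.null(get(nm)))
        stop("configuration missing required key: ", nm,
             " (or provide a simulation block)")
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full co-expression pipeline
#'
#' Executes filter -> network -> modules -> eigengenes -> trait
#' association -> hubs -> cell-type enrichment -> differential expression
#' -> external DEG overlap (when an external list is configured). Any
#' stage failure aborts with the stage name. When `output_dir` is set, all
#' result tables are written as TSV together with `run_log.txt` recording
#' package version and every parameter in effect; identical configurations
#' produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `expression` (post-QC),
#'   `samples`, `filter_report`, `power_selection`, `partition`,
#'   `eigengenes`, `module_trait` (diagnosis and time associations),
#'   `significant_modules`, `connectivity` (with hub flags), `enrichment`,
#'   `de` (DE result table), `deg_overlap` (or NULL), `edges` (per
#'   significant module), `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config object")
  cf <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- NULL
  if (!is.null(cf$simulation)) {
    sim <- stage("simulate", generate_dataset(cf$simulation))
    x <- sim$expression
    samples <- sim$samples
    gene_sets <- sim$gene_sets
  } else {
    x <- stage("read", read_expression_tsv(cf$expression_file))
    samples <- stage("read", read_sample_tsv(cf$sample_file))
    gene_sets <- if (!is.null(cf$gene_sets_file))
      stage("read", read_gmt(cf$gene_sets_file)) else NULL
  }

  filt <- stage("filter", preprocess_expression(
    x, samples, max_threshold = cf$max_threshold, level = cf$level,
    fraction = cf$fraction, rule = cf$prevalence_rule))
  xq <- filt$expression

  C <- stage("network", correlation_matrix(xq))
  ps <- stage("network", soft_threshold_scan(C, cf$powers, cf$r2_threshold))
  A <- stage("network", adjacency_matrix(C, ps$chosen_power))
  W <- if (cf$dissimilarity == "tom")
    stage("network", topological_overlap(A)) else A
  tree <- stage("network", build_dendrogram(local({
    D <- 1 - W
    diag(D) <- 0
    D
  })))
  part <- stage("modules", dynamic_tree_cut(
    tree, cf$min_module_size, cf$deep_split, cf$cut_height_fraction))
  eig <- stage("eigengenes", module_eigengenes(xq, part))

  assoc_dx <- stage("associate", module_trait_association(
    eig, samples, "diagnosis", cf$module_alpha))
  assoc_time <- if ("time_since_event" %in% names(samples))
    stage("associate", module_trait_association(
      eig, samples, "time_since_event", cf$module_alpha)) else NULL
  sig_mods <- assoc_dx$module[assoc_dx$significant]

  conn <- stage("hubs", identify_hubs(
    intramodular_connectivity(A, part), cf$hub_fraction))

  enr <- if (!is.null(gene_sets) && length(module_sizes(part)) > 0)
    stage("enrich", celltype_enrichment(part, gene_sets, rownames(xq),
                                        cf$module_alpha)) else NULL

  de <- stage("de", differential_expression(
    xq, samples, design_spec(), cf$fdr_threshold, cf$fc_threshold))

  ov <- if (!is.null(cf$external_degs))
    stage("overlap", deg_overlap(de$gene_id[de$significant],
                                 cf$external_degs, rownames(xq))) else NULL

  edges <- lapply(stats::setNames(sig_mods, sig_mods), function(m)
    stage("export-edges", export_edges(W, part, m, cf$min_edge_weight,
                                       cf$max_edges)))

  res <- structure(list(
    expression = xq, samples = samples, filter_report = filt$report,
    power_selection = ps, partition = part, eigengenes = eig,
    module_trait = list(diagnosis = assoc_dx, time = assoc_time),
    significant_modules = sig_mods, connectivity = conn, enrichment = enr,
    de = de, deg_overlap = ov, edges = edges, truth = sim$truth,
    config = cf), class = "pipeline_result")

  if (!is.null(cf$output_dir)) write_pipeline_results(res, cf$output_dir)
  res
}

#' Write every pipeline artifact to a directory
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(res$expression, p("filtered_expression.tsv"))
  write_sample_tsv(res$samples, p("samples.tsv"))
  write_filter_report(res$filter_report, p("filter_report.tsv"))
  write_result_tsv(res$power_selection$scan, p("power_scan.tsv"))
  write_result_tsv(
    data.frame(gene_id = names(res$partition),
               module = as.character(res$partition)),
    p("module_assignments.tsv"))
  eig <- res$eigengenes$eigengenes
  write_result_tsv(
    data.frame(module = rownames(eig),
               variance_explained = res$eigengenes$variance_explained,
               as.data.frame(eig, check.names = FALSE)),
    p("eigengenes.tsv"))
  write_result_tsv(rbind(res$module_trait$diagnosis,
                         res$module_trait$time),
                   p("module_trait.tsv"))
  write_result_tsv(res$connectivity, p("connectivity.tsv"))
  if (!is.null(res$enrichment))
    write_result_tsv(res$enrichment, p("celltype_enrichment.tsv"))
  write_result_tsv(as.data.frame(res$de), p("de_results.tsv"))
  if (!is.null(res$deg_overlap)) {
    ov <- res$deg_overlap
    write_result_tsv(
      data.frame(n_universe = ov$n_universe, n_a = ov$n_a, n_b = ov$n_b,
                 overlap = ov$overlap, expected = ov$expected,
                 p_upper = ov$p_upper,
                 genes = paste(ov$intersection, collapse = ",")),
      p("deg_overlap.tsv"))
  }
  for (m in names(res$edges))
    write_result_tsv(res$edges[[m]], p(paste0("edges_", m, ".tsv")))
  writeLines(run_log_lines(res$config), p("run_log.txt"))
  invisible(dir)
}

# Flat key = value dump of every configuration entry; sufficient to
# reconstruct the run.
run_log_lines <- function(cf) {
  fmt1 <- function(v) {
    if (is.null(v)) return("NULL")
    if (inherits(v, "sim_config"))
      return(paste0("sim_config(",
                    paste(names(unclass(v)), vapply(unclass(v), fmt1,
                                                    character(1)),
                          sep = "=", collapse = ", "), ")"))
    paste(format(v, digits = 15), collapse = ",")
  }
  c(paste0("bloodcoex version: ",
           as.character(utils::packageVersion("bloodcoex"))),
    vapply(names(unclass(cf)), function(nm)
      paste0(nm, " = ", fmt1(cf[[nm]])), character(1)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Co-expression pipeline result\n")
  cat(sprintf("  %d genes x %d samples after QC\n", nrow(x$expression),
              ncol(x$expression)))
  cat(sprintf("  soft-threshold power: %d\n",
              x$power_selection$chosen_power))
  sz <- module_sizes(x$partition)
  cat(sprintf("  %d modules (sizes %s), %d grey\n", length(sz),
              paste(sz, collapse = ", "),
              sum(x$partition == "grey")))
  cat(sprintf("  diagnosis-significant modules: %s\n",
              if (length(x$significant_modules))
                paste(x$significant_modules, collapse = ", ") else "none"))
  cat(sprintf("  DE genes (FDR & FC rule): %d of %d\n",
              sum(x$de$significant), nrow(x$de)))
  invisible(x)
}
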