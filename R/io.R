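# Readers and writers for the pipeline's plain-text formats: expression
# TSV (gene_id + one column per sample), sample TSV, GMT gene sets, and
# the edge-list export for network visualization.

#' Read an expression matrix from TSV
#'
#' Expects one header row (`gene_id` then sample ids) and one row per gene.
#' Empty cells parse as missing; any other non-numeric cell is an error
#' naming its location; duplicate gene or sample ids are errors.
#'
#' @param path input file.
#' @return numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("expression TSV needs gene_id plus sample columns")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals == "" | is.na(vals)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene %s, sample %s",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write an expression matrix as TSV
#'
#' 12 significant digits, so a write/read round trip is stable to ~1e-9
#' relative; missing values are written as empty cells.
#'
#' @param x genes x samples numeric matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression(x)
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt_num(x[i, ], digits = 12L)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a sample table
#'
#' Tab-separated, one header row; columns sample_id, diagnosis, sex, age,
#' scan_date, time_since_event.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_tsv <- function(path) {
  s <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  check_samples(s)
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample id(s) in sample table")
  s
}

#' @rdname read_sample_tsv
#' @param samples sample table data.frame.
#' @export
write_sample_tsv <- function(samples, path) {
  check_samples(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are deduplicated (with a message);
#' duplicate set names and lines with fewer than 3 fields are errors.
#'
#' @param path GMT file.
#' @return named list of character vectors, with a parallel
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    if (f[1] %in% names(sets))
      stop("duplicate gene-set name: ", f[1])
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    u <- unique(members)
    n_dup <- n_dup + (length(members) - length(u))
    sets[[f[1]]] <- u
    desc[f[1]] <- f[2]
  }
  if (n_dup > 0)
    message(n_dup, " duplicate member(s) within sets were deduplicated")
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named descriptions; defaults to the set
#'   names.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm]))
      descriptions[nm] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export intramodular edges for network visualization
#'
#' Lists all within-module gene pairs whose network weight (adjacency or
#' topological overlap) reaches `min_weight`, sorted by descending weight
#' (ties by gene pair), truncated to `max_edges` rows. Each undirected
#' edge appears once with `gene_a < gene_b` lexicographically.
#'
#' @param W square weight matrix (adjacency or TOM) with gene dimnames.
#' @param partition gene -> module label vector.
#' @param module module label to export.
#' @param min_weight minimum weight retained; default 0.
#' @param max_edges row cap; default 10000.
#' @return data.frame: gene_a, gene_b, weight.
#' @export
export_edges <- function(W, partition, module, min_weight = 0,
                         max_edges = 10000) {
  if (!module %in% partition) stop("unknown module: ", module)
  genes <- sort(names(partition)[partition == module])
  genes <- intersect(genes, rownames(W))
  sub <- W[genes, genes, drop = FALSE]
  iu <- which(upper.tri(sub), arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[iu[, 1]], gene_b = genes[iu[, 2]],
                      weight = sub[iu], stringsAsFactors = FALSE)
  edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  utils::head(edges, max_edges)
}

# Generic result-table writer: TSV, one header row, floats at 6
# significant digits (bit-stable goldens).
write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
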