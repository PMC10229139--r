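#' Expression matrix container
#'
#' A gene-by-cell expression matrix with an explicit transform state. Genes
#' are rows and cells are columns everywhere in this package; both carry
#' unique identifiers. `transform` records whether the values are raw
#' (non-negative), `log2(x + 1)`-transformed, or per-gene z-scores.
#'
#' @param values numeric matrix, genes as rows, cells as columns. Dimnames
#'   are used as gene/cell identifiers when `gene_ids`/`cell_ids` are absent.
#' @param gene_ids,cell_ids optional character vectors of unique identifiers.
#' @param transform one of `"raw"`, `"log2"`, `"zscore"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              transform = c("raw", "log2", "zscore")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    validation_error("values must be a numeric matrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    validation_error("gene and cell identifiers are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    validation_error("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    validation_error("duplicate gene ids: ",
                     paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    validation_error("duplicate cell ids")
  if (transform == "raw" && any(values < 0, na.rm = TRUE))
    validation_error("raw expression values must be non-negative")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, transform = transform),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells, transform = %s\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
cell_ids <- function(m) colnames(m$values)

#' Load an expression matrix from disk
#'
#' Dense CSV/TSV files must have a header row of cell identifiers and gene
#' identifiers in the first column. The `mtx` format is matrix-market
#' coordinate (genes as rows) with companion one-column text files listing
#' gene and cell (barcode) identifiers.
#'
#' @param path file path (for `mtx`, the matrix file).
#' @param format `"csv"`, `"tsv"`, or `"mtx"`.
#' @param genes_path,barcodes_path companion identifier files, `mtx` only.
#' @param transform transform state to tag the loaded values with
#'   (default `"raw"`).
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, format = c("csv", "tsv", "mtx"),
                            genes_path = NULL, barcodes_path = NULL,
                            transform = "raw") {
  format <- match.arg(format)
  if (!file.exists(path)) validation_error("file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        row.names = NULL, stringsAsFactors = FALSE),
      error = function(e) parse_error("malformed ", format, " file ", path,
                                      ": ", conditionMessage(e))
    )
    if (ncol(df) < 2L) parse_error("no cell columns in ", path)
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!apply(df[, -1L, drop = FALSE], 1L,
                          function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
      parse_error("non-numeric expression values in ", path,
                  " at data line ", if (length(bad)) bad[1L] else NA)
    }
    expression_matrix(vals, gene_ids = ids, cell_ids = colnames(df)[-1L],
                      transform = transform)
  } else {
    if (is.null(genes_path) || is.null(barcodes_path))
      validation_error("mtx format requires genes_path and barcodes_path")
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) parse_error("malformed matrix-market file ",
                                                   path, ": ", conditionMessage(e)))
    genes <- readLines(genes_path)
    cells <- readLines(barcodes_path)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (length(genes) != nrow(mm) || length(cells) != ncol(mm))
      validation_error("gene/barcode list lengths do not match matrix dimensions")
    expression_matrix(as.matrix(mm), gene_ids = genes, cell_ids = cells,
                      transform = transform)
  }
}

#' Transform an expression matrix
#'
#' `log2` applies `log2(x + 1)` elementwise and requires raw input; `zscore`
#' standardizes each gene row to mean 0 and unit sample variance (constant
#' rows map to all zeros).
#'
#' @param m an [expression_matrix()].
#' @param mode `"log2"` or `"zscore"`.
#' @return A transformed [expression_matrix()].
#' @export
transform_expression <- function(m, mode = c("log2", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expression_matrix"))
  if (mode == "log2") {
    if (m$transform != "raw")
      state_error("log2 transform requires raw data (got ", m$transform, ")")
    expression_matrix(log2(m$values + 1), transform = "log2")
  } else {
    v <- m$values
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    expression_matrix(z, transform = "zscore")
  }
}

#' Per-gene attributes: mean, detection rate, variance, fold change
#'
#' Computes, for each gene of the case matrix, the mean expression, the
#' fraction of cells with expression strictly greater than zero, and the
#' sample variance. When a control matrix is given, a log2 fold change
#' `log2((mean_case + 1) / (mean_ctrl + 1))` is added for genes present in
#' the control; a transcription-factor list adds a logical `is_tf` column.
#'
#' @param case an [expression_matrix()].
#' @param control optional [expression_matrix()] with the same convention.
#' @param tf_list optional character vector of transcription-factor gene ids.
#' @return A data.frame with one row per case gene: `gene`, `mean_expr`,
#'   `pct_cells`, `variance`, and optionally `log_fc`, `is_tf`.
#' @export
compute_gene_attributes <- function(case, control = NULL, tf_list = NULL) {
  stopifnot(inherits(case, "expression_matrix"))
  if (nrow(case$values) == 0L || ncol(case$values) == 0L)
    validation_error("case matrix is empty")
  v <- case$values
  out <- data.frame(
    gene = gene_ids(case),
    mean_expr = rowMeans(v),
    pct_cells = rowMeans(v > 0),
    variance = apply(v, 1L, stats::var),
    stringsAsFactors = FALSE
  )
  if (ncol(v) == 1L) out$variance <- rep(0, nrow(v))
  if (!is.null(control)) {
    stopifnot(inherits(control, "expression_matrix"))
    if (ncol(control$values) == 0L)
      validation_error("control matrix has zero cells")
    ctrl_mean <- rowMeans(control$values)
    idx <- match(out$gene, gene_ids(control))
    out$log_fc <- log2((out$mean_expr + 1) / (ctrl_mean[idx] + 1))
  }
  if (!is.null(tf_list)) out$is_tf <- out$gene %in% tf_list
  rownames(out) <- NULL
  out
}

#' Gene filter specification
#'
#' Thresholds are combined by conjunction and compared strictly (`>`). The
#' packaged defaults follow the usual screen for highly and differentially
#' expressed genes: mean expression > 0.1, expressed in > 50% of cells, and
#' absolute log fold change > 0.3.
#'
#' @param min_mean_expr,min_pct_cells,min_variance,min_abs_log_fc optional
#'   finite numeric thresholds.
#' @param tf_only optional logical; keep transcription factors only.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_mean_expr = NULL, min_pct_cells = NULL,
                        min_variance = NULL, min_abs_log_fc = NULL,
                        tf_only = NULL) {
  spec <- list(min_mean_expr = min_mean_expr, min_pct_cells = min_pct_cells,
               min_variance = min_variance, min_abs_log_fc = min_abs_log_fc,
               tf_only = tf_only)
  set <- !vapply(spec, is.null, logical(1L))
  if (!any(set)) validation_error("filter_spec needs at least one condition")
  for (nm in names(spec)[set & names(spec) != "tf_only"])
    stopifnot_scalar_number(spec[[nm]], nm)
  structure(spec, class = "filter_spec")
}

#' Default filter thresholds for highly/differentially expressed genes
#' @return A [filter_spec()] with `min_mean_expr = 0.1`,
#'   `min_pct_cells = 0.5`, `min_abs_log_fc = 0.3`.
#' @export
default_filter_spec <- function() {
  filter_spec(min_mean_expr = 0.1, min_pct_cells = 0.5, min_abs_log_fc = 0.3)
}

#' Filter candidate genes on attribute thresholds
#'
#' Applies the conjunction of all conditions set in `spec` (strict `>`), and
#' returns the surviving gene ids ordered by `order_by` descending, ties
#' broken by gene id.
#'
#' @param attrs attribute table from [compute_gene_attributes()].
#' @param spec a [filter_spec()].
#' @param order_by attribute column to order by (default `"mean_expr"`).
#' @return Character vector of gene ids.
#' @export
filter_genes <- function(attrs, spec, order_by = "mean_expr") {
  stopifnot(inherits(spec, "filter_spec"), is.data.frame(attrs))
  keep <- rep(TRUE, nrow(attrs))
  need <- function(col, what) {
    if (is.null(attrs[[col]]))
      validation_error(what, " threshold set but attrs lack '", col, "'")
    attrs[[col]]
  }
  if (!is.null(spec$min_mean_expr))
    keep <- keep & need("mean_expr", "mean expression") > spec$min_mean_expr
  if (!is.null(spec$min_pct_cells))
    keep <- keep & need("pct_cells", "percent cells") > spec$min_pct_cells
  if (!is.null(spec$min_variance))
    keep <- keep & need("variance", "variance") > spec$min_variance
  if (!is.null(spec$min_abs_log_fc))
    keep <- keep & abs(need("log_fc", "fold change")) > spec$min_abs_log_fc
  if (isTRUE(spec$tf_only))
    keep <- keep & need("is_tf", "tf_only")
  keep[is.na(keep)] <- FALSE
  if (!order_by %in% names(attrs))
    validation_error("unknown ordering attribute '", order_by, "'")
  sel <- attrs[keep, , drop = FALSE]
  sel <- sel[order(-xtfrm(sel[[order_by]]), sel$gene), , drop = FALSE]
  sel$gene
}

#' Sub-sample cells
#'
#' Takes `n` cells without replacement, either a seeded random subset or the
#' first `n` columns. The suggested sizes are 300 cells for plate-based
#' (Smart-seq2) and 600 for droplet-based (10x) data at ~50 genes.
#'
#' @param m an [expression_matrix()].
#' @param n number of cells to keep, at most the current cell count.
#' @param mode `"random"` or `"first"`.
#' @param seed integer seed for `mode = "random"`.
#' @return An [expression_matrix()] with `n` cells.
#' @export
sample_cells <- function(m, n, mode = c("random", "first"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expression_matrix"))
  nc <- ncol(m$values)
  if (!is.numeric(n) || n < 1L || n != round(n))
    validation_error("n must be a positive integer")
  if (n > nc)
    validation_error("n = ", n, " exceeds the cell count ", nc)
  idx <- if (n == nc) seq_len(nc)
         else if (mode == "first") seq_len(n)
         else with_seed(seed, sort(sample.int(nc, n)))
  out <- m
  out$values <- m$values[, idx, drop = FALSE]
  out
}

#' Write a gene attribute table as TSV
#' @param attrs table from [compute_gene_attributes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_attributes <- function(attrs, path) {
  utils::write.table(attrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as CSV (genes as rows)
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = gene_ids(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
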