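#' Cells-by-genes expression matrix with a per-cell miRNA proxy
#'
#' The central data container: a numeric matrix of non-negative abundances
#' with cells in rows and genes in columns, plus a per-cell scalar `proxy`
#' that tracks the miRNA level (the true total Ago-miRNA for synthetic data,
#' or a co-induced reporter such as GFP for real data).
#'
#' @param values numeric matrix, cells x genes, entries `>= 0`.
#' @param proxy numeric vector, one non-negative value per cell.
#' @param cell_ids,gene_ids optional id vectors (default from dimnames or
#'   generated).
#' @param gene_type optional character vector per gene, e.g. `"target"` /
#'   `"background"`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, proxy, cell_ids = NULL, gene_ids = NULL,
                              gene_type = NULL) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stopf("expression values must be >= 0")
  if (length(proxy) != nrow(values)) {
    stopf("'proxy' must have one value per cell (row)")
  }
  if (any(proxy < 0)) stopf("'proxy' must be >= 0")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  }
  if (nrow(values) > 0) rownames(values) <- cell_ids
  if (ncol(values) > 0) colnames(values) <- gene_ids
  structure(
    list(values = values, proxy = stats::setNames(as.numeric(proxy), cell_ids),
         gene_type = gene_type),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d cells x %d genes; proxy range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), min(x$proxy), max(x$proxy)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Order the cells of an expression matrix by proxy value
#'
#' Stable sort: proxy ties keep the original cell order, so repeated runs on
#' the same matrix are deterministic.
#'
#' @param mat an [expression_matrix()].
#' @param decreasing sort direction.
#' @return the matrix with rows (cells) reordered.
#' @export
order_by_proxy <- function(mat, decreasing = FALSE) {
  o <- order(mat$proxy, decreasing = decreasing)
  subset_cells(mat, o)
}

#' Subset helper functions for expression matrices
#'
#' @param mat an [expression_matrix()].
#' @param i cell (row) index or id vector.
#' @param j gene (column) index or id vector.
#' @return a new `ExpressionMatrix`.
#' @export
subset_cells <- function(mat, i) {
  expression_matrix(mat$values[i, , drop = FALSE], mat$proxy[i],
                    gene_type = mat$gene_type)
}

#' @rdname subset_cells
#' @export
subset_genes <- function(mat, j) {
  if (is.character(j)) j <- match(j, colnames(mat$values))
  gt <- if (is.null(mat$gene_type)) NULL else mat$gene_type[j]
  expression_matrix(mat$values[, j, drop = FALSE], mat$proxy, gene_type = gt)
}
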