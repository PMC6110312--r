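# Matrix I/O and the study's preprocessing: counts-per-million
# normalization with pseudocounts and the low-expression filter. On-disk
# orientation is genes x cells (the droplet-sequencing convention); in
# memory the package works cells x genes.

#' Read a cell-by-gene expression matrix
#'
#' Supports a plain TSV (genes in rows, cells in columns, gene ids in the
#' first column, cell ids in the header) and MatrixMarket triplets with id
#' side files (one gene id per line, one cell id per line). The per-cell
#' miRNA proxy is taken either from a designated gene row (e.g. the GFP
#' reporter; the row is removed from the gene panel) or from a two-column
#' TSV (`cell`, `proxy`).
#'
#' @param path matrix file (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @param genes_file,cells_file id side files (required for `"mtx"`).
#' @param proxy_gene gene id whose row supplies the proxy.
#' @param proxy_file per-cell proxy TSV (alternative to `proxy_gene`).
#' @return an [expression_matrix()] (cells x genes).
#' @export
read_expression_matrix <- function(path, format = NULL,
                                   genes_file = NULL, cells_file = NULL,
                                   proxy_gene = NULL, proxy_file = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  format <- match.arg(format, c("tsv", "mtx"))
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    cell_ids <- colnames(vals)
  } else {
    if (is.null(genes_file) || is.null(cells_file)) {
      stopf("MatrixMarket input needs 'genes_file' and 'cells_file'")
    }
    vals <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_file)
    cell_ids <- readLines(cells_file)
    if (nrow(vals) != length(gene_ids) || ncol(vals) != length(cell_ids)) {
      stopf("dimension mismatch between matrix (%d x %d) and id files (%d genes, %d cells)",
            nrow(vals), ncol(vals), length(gene_ids), length(cell_ids))
    }
  }
  if (any(vals < 0)) stopf("negative counts in matrix")
  vals <- t(vals) # cells x genes in memory
  colnames(vals) <- gene_ids
  rownames(vals) <- cell_ids
  proxy <- rep(0, nrow(vals))
  if (!is.null(proxy_gene)) {
    if (!proxy_gene %in% gene_ids) {
      stopf("proxy gene '%s' not found in matrix", proxy_gene)
    }
    proxy <- vals[, proxy_gene]
    vals <- vals[, setdiff(gene_ids, proxy_gene), drop = FALSE]
  } else if (!is.null(proxy_file)) {
    pf <- utils::read.delim(proxy_file, stringsAsFactors = FALSE)
    proxy <- pf[[2]][match(cell_ids, as.character(pf[[1]]))]
    if (anyNA(proxy)) stopf("proxy file does not cover all cells")
  }
  out <- expression_matrix(vals, proxy = proxy)
  attr(out, "proxy_gene") <- proxy_gene
  out
}

#' Write an expression matrix
#'
#' @param mat an [expression_matrix()].
#' @param path output matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_file,cells_file side-file paths for `"mtx"` (defaults next
#'   to `path`).
#' @return `path` invisibly.
#' @export
write_expression_matrix <- function(mat, path, format = c("tsv", "mtx"),
                                    genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  vals <- t(mat$values) # genes x cells on disk
  if (format == "tsv") {
    df <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(genes_file)) genes_file <- paste0(path, ".genes.tsv")
    if (is.null(cells_file)) cells_file <- paste0(path, ".cells.tsv")
    Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE), path)
    writeLines(rownames(vals), genes_file)
    writeLines(colnames(vals), cells_file)
  }
  invisible(path)
}

#' Counts-per-million normalization with pseudocounts
#'
#' Scales each cell to one million counts (the total includes the proxy
#' gene's counts when a proxy is present), then adds a small pseudocount to
#' every gene value (default 0.001) and a larger one to the proxy
#' (default 1.0, so miRNA-free cells sit at exactly 1 on the proxy axis).
#' Cells with zero total count are dropped with a warning.
#'
#' @param mat an [expression_matrix()] of raw counts, proxy = raw proxy-gene
#'   counts.
#' @param gene_pseudocount added to every normalized gene value.
#' @param proxy_pseudocount added to the normalized proxy value.
#' @param include_proxy_in_total whether the proxy gene's counts enter the
#'   per-cell total (default `TRUE` when any proxy count is non-zero).
#' @return a normalized [expression_matrix()].
#' @export
normalize_cpm <- function(mat, gene_pseudocount = 0.001,
                          proxy_pseudocount = 1.0,
                          include_proxy_in_total = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.null(include_proxy_in_total)) {
    include_proxy_in_total <- any(mat$proxy > 0)
  }
  totals <- rowSums(mat$values) +
    if (include_proxy_in_total) mat$proxy else 0
  keep <- totals > 0
  if (!all(keep)) {
    warnf("dropped %d cell(s) with zero total count", sum(!keep))
    mat <- subset_cells(mat, which(keep))
    totals <- totals[keep]
  }
  vals <- mat$values / totals * 1e6 + gene_pseudocount
  proxy <- mat$proxy / totals * 1e6 + proxy_pseudocount
  out <- expression_matrix(vals, proxy = proxy, gene_type = mat$gene_type)
  attr(out, "normalized") <- "cpm"
  out
}

#' Drop genes with very low mean expression
#'
#' Removes genes whose across-cell mean normalized expression is strictly
#' below `min_mean` (default 7). The proxy is a separate per-cell field and
#' is never filtered.
#'
#' @param mat a normalized [expression_matrix()].
#' @param min_mean threshold on the across-cell mean (strict `<`).
#' @return the filtered [expression_matrix()].
#' @export
filter_low_expression <- function(mat, min_mean = 7) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  keep <- colMeans(mat$values) >= min_mean
  if (!any(keep)) warnf("low-expression filter removed every gene")
  subset_genes(mat, unname(which(keep)))
}
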