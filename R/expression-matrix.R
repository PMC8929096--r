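#' Expression matrix container
#'
#' Light container for a sparse gene-by-cell count matrix with optional
#' per-cell metadata, the object every downstream stage consumes.
#'
#' @param counts sparse (or dense) nonnegative matrix, genes in rows and
#'   cells in columns, with unique row and column names.
#' @param meta optional `data.frame` of per-cell annotations (e.g. `batch`,
#'   `known_type`), one row per cell in column order of `counts`.
#' @return an object of class `sc_expression` with elements `counts`,
#'   `gene_ids`, `cell_ids` and `meta`.
#' @export
sc_expression <- function(counts, meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene IDs in counts")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate cell IDs in counts")
  if (any(counts@x < 0)) stopf("counts must be nonnegative")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != ncol(counts))
      stopf("meta has %d rows but counts has %d cells", nrow(meta), ncol(counts))
    rownames(meta) <- colnames(counts)
  }
  structure(
    list(counts = counts,
         gene_ids = rownames(counts),
         cell_ids = colnames(counts),
         meta = meta),
    class = "sc_expression")
}

#' @export
print.sc_expression <- function(x, ...) {
  cat(sprintf("<sc_expression> %d genes x %d cells (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  if (!is.null(x$meta))
    cat("  meta:", paste(colnames(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sc_expression <- function(x) dim(x$counts)

#' Subset an expression matrix to a set of cells
#'
#' @param m an [sc_expression] object.
#' @param cells character vector of cell IDs (must all be present).
#' @return an [sc_expression] restricted to `cells`, in the given order.
#' @export
subset_cells <- function(m, cells) {
  miss <- setdiff(cells, m$cell_ids)
  if (length(miss))
    stopf("unknown cell IDs: %s%s", paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) ", ..." else "")
  sc_expression(m$counts[, cells, drop = FALSE],
                meta = if (!is.null(m$meta)) m$meta[cells, , drop = FALSE])
}
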