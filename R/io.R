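# Reading and writing count matrices (10x-style MatrixMarket triplet
# directories and dense TSV) and ladder/ground-truth tables.

#' Read a count matrix
#'
#' Supports a 10x-style directory (`matrix.mtx` in 1-based MatrixMarket
#' coordinate form, genes x cells, plus `features.tsv` and `barcodes.tsv`)
#' or a dense TSV (genes in rows, first column gene IDs, header of cell
#' IDs). Malformed headers, 0-based indices, out-of-range entries and
#' ID/dimension mismatches raise explicit errors.
#'
#' @param path directory (MTX) or file (TSV).
#' @param format `"auto"` (directory -> mtx, file -> tsv), `"mtx"` or
#'   `"tsv"`.
#' @return an [sc_expression].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx" else "tsv"
  if (format == "mtx") read_counts_mtx(path) else read_counts_tsv(path)
}

read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  bars <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feats, bars))
    if (!file.exists(f)) stopf("missing file: %s", f)

  head_lines <- readLines(mtx, n = 100)
  if (!grepl("^%%MatrixMarket +matrix +coordinate +(integer|real) +general",
             head_lines[1]))
    stopf("line 1 of %s: not a MatrixMarket coordinate header: '%s'",
          mtx, head_lines[1])
  n_comment <- which(!startsWith(head_lines, "%"))[1] - 1L
  if (is.na(n_comment)) stopf("%s: no dimensions line found", mtx)
  dims <- suppressWarnings(as.numeric(strsplit(
    trimws(head_lines[n_comment + 1L]), "[ \t]+")[[1]]))
  if (length(dims) != 3 || any(is.na(dims)))
    stopf("line %d of %s: malformed dimensions line", n_comment + 1L, mtx)

  trip <- data.table::fread(mtx, skip = n_comment + 1L, header = FALSE,
                            col.names = c("i", "j", "x"))
  if (nrow(trip) != dims[3])
    stopf("%s: header promises %d entries, found %d", mtx, dims[3], nrow(trip))
  if (nrow(trip) && min(trip$i, trip$j) < 1L)
    stopf("%s: found index 0; MatrixMarket coordinate files are 1-based", mtx)
  if (nrow(trip) && (max(trip$i) > dims[1] || max(trip$j) > dims[2]))
    stopf("%s: entry index exceeds declared dimensions %d x %d",
          mtx, dims[1], dims[2])

  gene_ids <- data.table::fread(feats, header = FALSE)[[1]]
  barcodes <- data.table::fread(bars, header = FALSE)[[1]]
  if (length(gene_ids) != dims[1])
    stopf("features.tsv has %d rows but matrix declares %d genes",
          length(gene_ids), dims[1])
  if (length(barcodes) != dims[2])
    stopf("barcodes.tsv has %d rows but matrix declares %d cells",
          length(barcodes), dims[2])
  if (anyDuplicated(barcodes)) stopf("duplicate barcodes in %s", bars)
  if (anyDuplicated(gene_ids)) stopf("duplicate gene IDs in %s", feats)

  counts <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = as.numeric(trip$x),
                                 dims = dims[1:2],
                                 dimnames = list(gene_ids, barcodes))
  sc_expression(counts)
}

read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  gene_ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  rownames(mat) <- gene_ids
  sc_expression(methods::as(mat, "CsparseMatrix"))
}

#' Write a count matrix
#'
#' Writes either a 10x-style triplet directory (`matrix.mtx` with 1-based
#' indices, genes x cells; `features.tsv`; `barcodes.tsv`) or a dense TSV.
#' `read_counts(write_counts(m))` reproduces `m` exactly.
#'
#' @param m an [sc_expression].
#' @param path output directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(m, "sc_expression"))
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::data.table(gene = m$gene_ids)
    dt <- cbind(dt, data.table::as.data.table(as.matrix(m$counts)))
    data.table::setnames(dt, c("gene", m$cell_ids))
    data.table::fwrite(dt, path, sep = "\t")
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  x <- methods::as(m$counts, "TsparseMatrix")
  integerish <- all(x@x == round(x@x))
  con <- file(file.path(path, "matrix.mtx"), "w")
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                       if (integerish) "integer" else "real"),
               "%",
               sprintf("%d %d %d", nrow(x), ncol(x), length(x@x))), con)
  close(con)
  trip <- data.table::data.table(i = x@i + 1L, j = x@j + 1L,
                                 x = if (integerish) as.integer(x@x) else x@x)
  data.table::setorder(trip, j, i)
  data.table::fwrite(trip, file.path(path, "matrix.mtx"), sep = " ",
                     append = TRUE, col.names = FALSE)
  data.table::fwrite(
    data.table::data.table(id = m$gene_ids, name = m$gene_ids,
                           type = "Gene Expression"),
    file.path(path, "features.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::data.table(bc = m$cell_ids),
                     file.path(path, "barcodes.tsv"), sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write ladder membership as TSV (size, cell_id)
#' @param ladder an `sc_ladder`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  dt <- data.table::rbindlist(lapply(names(ladder$draws), function(s)
    data.table::data.table(size = as.integer(s), cell_id = ladder$draws[[s]])))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write ground truth as TSV (cell_id, type, batch, pseudotime)
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  dt <- data.table::data.table(cell_id = names(truth$cell_type),
                               type = unname(truth$cell_type),
                               batch = unname(truth$batch),
                               pseudotime = unname(truth$pseudotime))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
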