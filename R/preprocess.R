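# Filtering, log-normalisation, highly-variable-gene selection and the
# seeded subsampling ladder that defines the whole experiment.

#' Filter genes and cells by detection
#'
#' Single-pass quality filter: genes detected (count > 0) in at least
#' `min_cells_per_gene` cells are retained first; then cells with at least
#' `min_genes_per_cell` retained genes are kept. The defaults (3 cells per
#' gene, 200 genes per cell) are the usual low-stringency droplet filter.
#' The operation is idempotent.
#'
#' @param m an [sc_expression].
#' @param min_cells_per_gene,min_genes_per_cell nonnegative thresholds.
#' @return the filtered [sc_expression].
#' @export
filter_matrix <- function(m, min_cells_per_gene = 3, min_genes_per_cell = 200) {
  stopifnot(inherits(m, "sc_expression"))
  if (min_cells_per_gene < 0 || min_genes_per_cell < 0)
    stopf("thresholds must be nonnegative")
  x <- m$counts
  keep_g <- Matrix::rowSums(x > 0) >= min_cells_per_gene
  if (!any(keep_g))
    stopf("no genes retained: none detected in >= %d cells", min_cells_per_gene)
  if (!all(keep_g)) x <- x[keep_g, , drop = FALSE]
  keep_c <- Matrix::colSums(x > 0) >= min_genes_per_cell
  if (!any(keep_c))
    stopf("no cells retained: none with >= %d expressed genes",
          min_genes_per_cell)
  if (all(keep_c) && all(keep_g)) return(m)   # idempotent case: no copies
  sc_expression(x[, keep_c, drop = FALSE],
                meta = if (!is.null(m$meta)) m$meta[keep_c, , drop = FALSE])
}

#' Log-normalise counts
#'
#' Per-cell depth normalisation followed by a log transform:
#' `value = ln(1 + scale_factor * count / depth)` with `depth` the cell's
#' total count. Zeros map to zero, so sparsity is preserved, and the map is
#' strictly monotone in counts within a cell.
#'
#' @param m an [sc_expression].
#' @param scale_factor pseudo-depth every cell is scaled to (default 10000).
#' @return an object of class `sc_norm` with elements `values` (sparse
#'   log-normalised genes x cells), `counts` (the input counts, kept for
#'   detection-based statistics), `scale_factor`, `hvg_ids` (`NULL` until
#'   [select_hvg()] is applied) and `meta`.
#' @export
normalize_log <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "sc_expression"))
  depth <- Matrix::colSums(m$counts)
  if (any(depth == 0)) {
    bad <- m$cell_ids[depth == 0]
    stopf("zero-depth cells cannot be normalised: %s%s",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(", ... (%d total)", length(bad)) else "")
  }
  v <- m$counts %*% Matrix::Diagonal(ncol(m$counts), scale_factor / depth)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$counts)
  structure(
    list(values = v, counts = m$counts, scale_factor = scale_factor,
         hvg_ids = NULL, meta = m$meta),
    class = "sc_norm")
}

#' @export
print.sc_norm <- function(x, ...) {
  cat(sprintf("<sc_norm> %d genes x %d cells, scale_factor = %g, %s HVGs\n",
              nrow(x$values), ncol(x$values), x$scale_factor,
              if (is.null(x$hvg_ids)) "no" else length(x$hvg_ids)))
  invisible(x)
}

#' Subset a normalised matrix to a set of cells
#' @param nm an `sc_norm`.
#' @param cells character vector of cell IDs.
#' @return an `sc_norm` restricted to `cells` (HVG selection is dropped and
#'   should be recomputed on the subsample).
#' @export
subset_norm <- function(nm, cells) {
  miss <- setdiff(cells, colnames(nm$values))
  if (length(miss)) stopf("unknown cell IDs: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  structure(
    list(values = nm$values[, cells, drop = FALSE],
         counts = nm$counts[, cells, drop = FALSE],
         scale_factor = nm$scale_factor,
         hvg_ids = NULL,
         meta = if (!is.null(nm$meta)) nm$meta[cells, , drop = FALSE]),
    class = "sc_norm")
}

# Variance-stabilised per-gene dispersion on raw counts: fit the
# mean-variance trend by local regression in log10 space, standardise each
# observation by the trend's SD with clipping at sqrt(n_cells), and report
# the variance of the clipped z-scores.
vst_standardized_variance <- function(counts, loess_span = 0.3) {
  n <- ncol(counts); g <- nrow(counts)
  mu <- Matrix::rowSums(counts) / n
  i <- counts@i + 1L
  ssq <- numeric(g)
  if (length(i)) {
    acc <- rowsum(counts@x^2, i)
    ssq[as.integer(rownames(acc))] <- acc[, 1]
  }
  v <- (ssq - n * mu^2) / (n - 1)
  fit_ok <- v > 0 & mu > 0
  sd_hat <- rep(0, g)
  if (sum(fit_ok) < 10) {
    sd_hat[fit_ok] <- sqrt(v[fit_ok])      # too few genes for a trend
  } else {
    fit <- stats::loess(log10(v[fit_ok]) ~ log10(mu[fit_ok]),
                        span = loess_span, degree = 2,
                        family = "gaussian")
    sd_hat[fit_ok] <- sqrt(10^stats::fitted(fit))
  }
  clip <- sqrt(n)
  nnz <- tabulate(i, nbins = g)
  z <- (counts@x - mu[i]) / sd_hat[i]
  z <- pmin(pmax(z, -clip), clip)
  z[!is.finite(z)] <- 0
  acc <- rep(0, g)
  if (length(z)) {
    s <- rowsum(z^2, i)
    acc[as.integer(rownames(s))] <- s[, 1]
  }
  z0 <- ifelse(sd_hat > 0, pmin(pmax(-mu / sd_hat, -clip), clip), 0)
  out <- (acc + (n - nnz) * z0^2) / (n - 1)
  out[sd_hat == 0] <- 0
  names(out) <- rownames(counts)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by variance-stabilised dispersion: the per-gene variance of
#' count z-scores standardised against a local-regression mean-variance
#' trend (log10 space), clipped at `sqrt(n_cells)`. Constant genes score 0
#' and are never selected while informative genes remain.
#'
#' @param nm an `sc_norm`.
#' @param n_top number of genes to record as HVGs (`<=` number of genes).
#' @return `nm` with `hvg_ids` set (decreasing standardised variance) and a
#'   `hvg_variance` attribute carrying the full ranking.
#' @export
select_hvg <- function(nm, n_top = 2000) {
  stopifnot(inherits(nm, "sc_norm"))
  g <- nrow(nm$values)
  if (n_top > g) stopf("n_top (%d) exceeds number of genes (%d)", n_top, g)
  sv <- vst_standardized_variance(nm$counts)
  ord <- order(sv, decreasing = TRUE)
  nm$hvg_ids <- rownames(nm$values)[ord[seq_len(n_top)]]
  attr(nm, "hvg_variance") <- sv
  nm
}

#' Build a subsampling ladder
#'
#' Draws uniform, without-replacement cell subsets of increasing sizes from
#' a pool. In `independent` mode each size is drawn separately from a
#' size-indexed seed stream (each subsample is an independent draw from the
#' pool); in `nested` mode the draws are prefixes of one seeded permutation,
#' so smaller draws are subsets of larger ones.
#'
#' @param pool an [sc_expression] or `sc_norm` (the pool of cells).
#' @param sizes strictly increasing positive sizes, all `<=` pool size.
#' @param mode `"independent"` (default) or `"nested"`.
#' @param seed master seed (default 1234).
#' @return an object of class `sc_ladder`: `sizes`, `mode`, `seed`, and
#'   `draws`, a list of cell-ID vectors named by size.
#' @export
make_ladder <- function(pool, sizes, mode = c("independent", "nested"),
                        seed = 1234) {
  mode <- match.arg(mode)
  ids <- if (inherits(pool, "sc_expression")) pool$cell_ids
         else if (inherits(pool, "sc_norm")) colnames(pool$values)
         else as.character(pool)
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stopf("sizes must be strictly increasing")
  if (any(sizes < 1)) stopf("sizes must be positive")
  if (max(sizes) > length(ids))
    stopf("largest size (%d) exceeds pool size (%d)", max(sizes), length(ids))
  draws <- if (mode == "nested") {
    perm <- with_seed(seed, sample(ids))
    lapply(sizes, function(s) perm[seq_len(s)])
  } else {
    lapply(seq_along(sizes), function(k)
      with_seed(derive_seed(seed, k), sample(ids, sizes[k])))
  }
  names(draws) <- as.character(sizes)
  structure(list(sizes = sizes, mode = mode, seed = as.integer(seed),
                 draws = draws),
            class = "sc_ladder")
}

#' The eight ladder sizes used throughout, plus the full pool
#'
#' @param pool_size number of cells in the pool.
#' @return increasing sizes: 500, 1000, 3000, 5000, 10000, 20000, 30000,
#'   40000 restricted to `< pool_size`, with `pool_size` appended.
#' @export
default_ladder_sizes <- function(pool_size) {
  s <- c(500L, 1000L, 3000L, 5000L, 10000L, 20000L, 30000L, 40000L)
  sort(unique(c(s[s < pool_size], as.integer(pool_size))))
}
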