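# PCA on scaled HVG expression, the Elbow heuristic, the JackStraw
# permutation test with the stop-at-first-nonsignificant PC counting rule,
# and correlation of top PCs between a subsample and the full pool.

# Dense per-gene z-scored HVG block with clipping at +/- `clip`. When a
# batch vector is given, per-batch per-gene means are removed first in log
# space -- the package's documented stand-in for anchor-based integration.
# With regress_depth, each gene is additionally residualised against the
# cell's log total count, removing the residual depth axis that survives
# per-cell normalisation.
scaled_hvg_matrix <- function(nm, clip = 10, batch = NULL,
                              regress_depth = FALSE) {
  stopifnot(inherits(nm, "sc_norm"))
  if (is.null(nm$hvg_ids)) stopf("run select_hvg() before PCA")
  Z <- as.matrix(nm$values[nm$hvg_ids, , drop = FALSE])
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != ncol(Z)) stopf("batch must have one entry per cell")
    for (b in unique(batch)) {
      j <- which(batch == b)
      Z[, j] <- Z[, j] - rowMeans(Z[, j, drop = FALSE])
    }
  }
  if (regress_depth) {
    cc <- log(Matrix::colSums(nm$counts))
    cc <- cc - mean(cc)
    if (sum(cc^2) > 0) {
      beta <- as.numeric(Z %*% cc) / sum(cc^2)
      Z <- Z - beta %o% cc
    }
  }
  mu <- rowMeans(Z)
  sd <- matrixStats::rowSds(Z)
  sd[sd == 0] <- 1
  # standardise and clip in column blocks: full-matrix arithmetic would
  # allocate several gene x cell temporaries at once
  for (j0 in seq(1, ncol(Z), by = 5000)) {
    j <- j0:min(j0 + 4999, ncol(Z))
    Z[, j] <- pmin(pmax((Z[, j] - mu) / sd, -clip), clip)
  }
  Z
}

# Truncated SVD: exact base svd for small problems, a gram-matrix
# eigendecomposition (BLAS-bound, fastest when genes << cells) at
# intermediate gene counts, Lanczos (irlba) with a deterministic internal
# RNG state otherwise.
truncated_svd <- function(Z, k) {
  if (min(dim(Z)) < max(3 * k, 50)) {
    s <- svd(Z, nu = k, nv = k)
    list(u = s$u[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)],
         v = s$v[, seq_len(k), drop = FALSE])
  } else if (min(dim(Z)) <= 3000) {
    if (nrow(Z) <= ncol(Z)) {
      e <- eigen(tcrossprod(Z), symmetric = TRUE)
      d <- sqrt(pmax(e$values[seq_len(k)], 0))
      u <- e$vectors[, seq_len(k), drop = FALSE]
      v <- sweep(crossprod(Z, u), 2, ifelse(d > 0, d, 1), `/`)
    } else {
      e <- eigen(crossprod(Z), symmetric = TRUE)
      d <- sqrt(pmax(e$values[seq_len(k)], 0))
      v <- e$vectors[, seq_len(k), drop = FALSE]
      u <- sweep(Z %*% v, 2, ifelse(d > 0, d, 1), `/`)
    }
    list(u = u, d = d, v = v)
  } else {
    with_seed(907, irlba::irlba(Z, nv = k, nu = k))
  }
}

# Streaming PCA for wide matrices: accumulates the gene x gene gram matrix
# over column blocks of the scaled HVG expression, so the dense
# genes x cells matrix never materialises. Mathematically identical to
# the dense gram path (same per-gene batch centering, optional depth
# regression, z-scoring and clipping).
stream_pca_gram <- function(nm, n_pcs, clip, batch, regress_depth,
                            block = 4000) {
  V <- nm$values[nm$hvg_ids, , drop = FALSE]
  g <- nrow(V); n <- ncol(V)
  bfac <- factor(if (is.null(batch)) rep("all", n) else as.character(batch))
  if (length(bfac) != n) stopf("batch must have one entry per cell")
  nb <- as.numeric(table(bfac))
  indB <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(bfac), x = 1,
                               dims = c(n, nlevels(bfac)))
  Mb <- sweep(as.matrix(V %*% indB), 2, nb, `/`)          # g x batches
  beta <- rep(0, g); cc <- rep(0, n)
  if (regress_depth) {
    cc <- log(Matrix::colSums(nm$counts))
    cc <- cc - mean(cc)
    ccs <- sum(cc^2)
    if (ccs > 0) {
      Cb <- as.numeric(tapply(cc, bfac, sum))
      beta <- (as.numeric(V %*% cc) - as.numeric(Mb %*% Cb)) / ccs
    }
  }
  ssq <- Matrix::rowSums(V^2)
  ss_centered <- ssq - as.numeric(Mb^2 %*% nb)
  res_ss <- pmax(ss_centered - beta^2 * sum(cc^2), 0)
  sd <- sqrt(res_ss / (n - 1))
  sd[sd == 0] <- 1

  bidx <- as.integer(bfac)
  load_block <- function(j) {
    Zb <- as.matrix(V[, j, drop = FALSE])
    Zb <- Zb - Mb[, bidx[j], drop = FALSE]
    if (any(beta != 0)) Zb <- Zb - beta %o% cc[j]
    Zb <- Zb / sd
    Zb[Zb > clip] <- clip
    Zb[Zb < -clip] <- -clip
    Zb
  }
  G <- matrix(0, g, g)
  zsum <- zsq <- rep(0, g)
  starts <- seq(1, n, by = block)
  for (s0 in starts) {
    j <- s0:min(s0 + block - 1, n)
    Zb <- load_block(j)
    G <- G + tcrossprod(Zb)
    zsum <- zsum + rowSums(Zb)
    zsq <- zsq + rowSums(Zb^2)
  }
  e <- eigen(G, symmetric = TRUE)
  d <- sqrt(pmax(e$values[seq_len(n_pcs)], 0))
  u <- e$vectors[, seq_len(n_pcs), drop = FALSE]
  v <- matrix(0, n, n_pcs)
  for (s0 in starts) {
    j <- s0:min(s0 + block - 1, n)
    v[j, ] <- crossprod(load_block(j), u)
  }
  v <- sweep(v, 2, ifelse(d > 0, d, 1), `/`)
  total_var <- sum((zsq - zsum^2 / n) / (n - 1))
  list(u = u, d = d, v = v, total_var = total_var,
       dimnames = list(rownames(V), colnames(V)))
}

#' Principal component analysis of a normalised matrix
#'
#' PCA of cells on per-gene z-scored HVG expression (z-scores clipped at
#' +/- 10). Loadings columns are unit norm with the sign convention that
#' each column's largest-magnitude entry is positive, making results
#' reproducible across linear-algebra backends.
#'
#' @param nm an `sc_norm` with `hvg_ids` set (see [select_hvg()]).
#' @param n_pcs number of components, `< min(n_cells, n_hvg)`.
#' @param clip z-score clipping bound.
#' @param batch optional per-cell batch labels; per-batch gene centering is
#'   applied before scaling (integration stand-in).
#' @param regress_depth residualise each gene against log total count
#'   before scaling, removing the library-depth axis that survives
#'   per-cell normalisation (default FALSE).
#' @param stream_threshold above this many cells, the scaled matrix is
#'   processed in column blocks (gram-matrix accumulation) instead of
#'   being held dense; results are identical up to numerical round-off.
#' @return an object of class `sc_pca`: `scores` (cells x PCs, rownames =
#'   cell IDs), `loadings` (genes x PCs), `variance_fraction` (per-PC share
#'   of total variance, nonincreasing).
#' @export
run_pca <- function(nm, n_pcs = 30, clip = 10, batch = NULL,
                    regress_depth = FALSE, stream_threshold = 20000) {
  n_cells <- ncol(nm$values)
  n_hvg <- length(nm$hvg_ids %||% character(0))
  if (n_pcs >= min(n_hvg, n_cells))
    stopf("n_pcs (%d) must be < min(n_hvg, n_cells) = %d",
          n_pcs, min(max(n_hvg, 1), n_cells))
  if (n_cells > stream_threshold && n_hvg <= 3000) {
    sv <- stream_pca_gram(nm, n_pcs, clip = clip, batch = batch,
                          regress_depth = regress_depth)
    dn <- sv$dimnames
    total_var <- sv$total_var
  } else {
    Z <- scaled_hvg_matrix(nm, clip = clip, batch = batch,
                           regress_depth = regress_depth)
    sv <- truncated_svd(Z, n_pcs)
    dn <- dimnames(Z)
    total_var <- sum(matrixStats::rowVars(Z))
  }
  # sign convention: dominant loading entry positive
  flip <- vapply(seq_len(n_pcs), function(j) {
    w <- sv$u[, j]; sign(w[which.max(abs(w))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$u, 2, flip, `*`)
  scores <- sweep(sv$v, 2, sv$d * flip, `*`)
  rownames(scores) <- dn[[2]]
  rownames(loadings) <- dn[[1]]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  structure(
    list(scores = scores, loadings = loadings,
         variance_fraction = sv$d^2 / ((n_cells - 1) * total_var),
         n_pcs = n_pcs),
    class = "sc_pca")
}

#' @export
print.sc_pca <- function(x, ...) {
  cat(sprintf("<sc_pca> %d cells x %d PCs (%.1f%% variance captured)\n",
              nrow(x$scores), x$n_pcs, 100 * sum(x$variance_fraction)))
  invisible(x)
}

#' Elbow (inflection) point of a scree curve
#'
#' Returns the component maximising the perpendicular distance to the
#' straight line joining the first and last points of the scree curve (the
#' kneedle construction). Deterministic; ties resolve to the smallest
#' index. When the scree is a straight line there is no elbow: the smallest
#' index is returned with attribute `no_clear_elbow = TRUE`.
#'
#' @param variance_fraction per-PC variance shares (or an `sc_pca`).
#' @return integer PC index, possibly with attribute `no_clear_elbow`.
#' @export
elbow_point <- function(variance_fraction) {
  if (inherits(variance_fraction, "sc_pca"))
    variance_fraction <- variance_fraction$variance_fraction
  v <- as.numeric(variance_fraction)
  p <- length(v)
  if (p < 3) stopf("elbow detection needs at least 3 PCs")
  x <- seq_len(p)
  # distance from (x, v) to the chord (1, v1)-(p, vp)
  dx <- p - 1; dy <- v[p] - v[1]
  d <- abs(dy * x - dx * v - dy * 1 + dx * v[1]) / sqrt(dx^2 + dy^2)
  k <- which.max(d)          # first index among exact ties
  scale <- max(d)
  out <- as.integer(k)
  if (scale <= 1e-12 * max(abs(v), 1e-300)) {
    out <- 1L
    attr(out, "no_clear_elbow") <- TRUE
  }
  out
}

#' JackStraw permutation test for significant PCs
#'
#' Per replicate, a random fraction of HVGs has its values permuted across
#' cells; PCA is recomputed and the permuted genes' squared loadings form
#' the null. A gene's empirical p-value per PC is the rank of its observed
#' squared loading in the pooled null; a PC's p-value is a one-sided exact
#' binomial test that the fraction of genes with p below `p_gene_thresh`
#' exceeds `p_gene_thresh`.
#'
#' @param nm an `sc_norm` with HVGs selected.
#' @param n_pcs PCs to test.
#' @param n_reps permutation replicates (>= 30).
#' @param perm_fraction fraction of HVGs permuted per replicate, in (0, 1]
#'   (1 destroys all structure and is useful for calibration checks).
#' @param seed integer seed.
#' @param p_gene_thresh gene-level threshold feeding the per-PC binomial
#'   enrichment test. The default (`NULL`) uses
#'   `max(1e-5, 10 / (null size + 1))`: empirical p-values cannot fall
#'   below `1/(null size + 1)`, so the threshold must sit above the null's
#'   resolution for the enrichment test to have any power, while staying
#'   small enough to keep it calibrated.
#' @param alpha PC-level significance threshold used for `n_significant`.
#' @param clip,batch,regress_depth passed to the PCA step.
#' @return an object of class `sc_jackstraw`: `gene_pvalues` (genes x PCs),
#'   `pc_pvalues`, `n_significant` (initial run of PCs with
#'   `p < alpha`, see [count_significant_pcs()]), `n_reps`,
#'   `perm_fraction`.
#' @export
jackstraw <- function(nm, n_pcs = 20, n_reps = 100, perm_fraction = 0.01,
                      seed = 1234, p_gene_thresh = NULL, alpha = 0.05,
                      clip = 10, batch = NULL, regress_depth = FALSE) {
  if (n_reps < 30) stopf("n_reps must be >= 30")
  if (perm_fraction <= 0 || perm_fraction > 1)
    stopf("perm_fraction must be in (0, 1]")
  Z <- scaled_hvg_matrix(nm, clip = clip, batch = batch,
                         regress_depth = regress_depth)
  g <- nrow(Z); n <- ncol(Z)
  if (n_pcs >= min(g, n)) stopf("n_pcs too large for %d x %d data", g, n)
  obs <- truncated_svd(Z, n_pcs)$u^2
  m <- max(1L, round(perm_fraction * g))
  null <- matrix(NA_real_, m * n_reps, n_pcs)
  for (r in seq_len(n_reps)) {
    with_seed(derive_seed(seed, r), {
      sel <- sample.int(g, m)
      Zp <- Z
      Zp[sel, ] <- t(apply(Z[sel, , drop = FALSE], 1, sample))
      null[(r - 1L) * m + seq_len(m), ] <- truncated_svd(Zp, n_pcs)$u[sel, ]^2
    })
  }
  N <- nrow(null)
  if (is.null(p_gene_thresh)) p_gene_thresh <- max(1e-5, 10 / (N + 1))
  pvals <- matrix(NA_real_, g, n_pcs,
                  dimnames = list(rownames(Z), paste0("PC", seq_len(n_pcs))))
  for (k in seq_len(n_pcs)) {
    sn <- sort(null[, k])
    n_ge <- N - findInterval(obs[, k], sn, left.open = TRUE)
    pvals[, k] <- (1 + n_ge) / (1 + N)
  }
  pc_p <- vapply(seq_len(n_pcs), function(k)
    stats::binom.test(sum(pvals[, k] < p_gene_thresh), g,
                      p = p_gene_thresh,
                      alternative = "greater")$p.value, numeric(1))
  structure(
    list(gene_pvalues = pvals, pc_pvalues = pc_p,
         n_significant = count_significant_pcs(pc_p, alpha),
         n_reps = n_reps, perm_fraction = perm_fraction),
    class = "sc_jackstraw")
}

#' Count significant PCs by the stop-at-first-failure rule
#'
#' The number of significant PCs is the length of the initial run of PCs
#' with `p < alpha`: once a PC fails the threshold, later PCs with small
#' p-values are no longer counted.
#'
#' @param pc_pvalues per-PC p-values in component order (or an
#'   `sc_jackstraw`).
#' @param alpha significance level in (0, 1).
#' @return integer count in `[0, length(pc_pvalues)]`.
#' @examples
#' count_significant_pcs(c(0.001, 0.01, 0.2, 0.03), 0.05)  # 2
#' @export
count_significant_pcs <- function(pc_pvalues, alpha = 0.05) {
  if (inherits(pc_pvalues, "sc_jackstraw"))
    pc_pvalues <- pc_pvalues$pc_pvalues
  p <- as.numeric(pc_pvalues)
  if (!length(p)) stopf("empty p-value vector")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  fail <- which(p >= alpha)
  if (!length(fail)) length(p) else fail[1] - 1L
}

#' Correlation grid between subsample and reference PCs
#'
#' Absolute Pearson correlation between a subsample's PC scores and a
#' reference's PC scores over their shared cells (top `n_top` PCs each).
#'
#' @param sub,ref `sc_pca` objects with cell IDs as score rownames.
#' @param shared_cells cells to use; defaults to the intersection.
#' @param n_top PCs per side (default 30, capped at what is available).
#' @return `n_top x n_top` matrix of absolute correlations (rows:
#'   subsample PCs, columns: reference PCs).
#' @export
pc_correlation <- function(sub, ref, shared_cells = NULL, n_top = 30) {
  stopifnot(inherits(sub, "sc_pca"), inherits(ref, "sc_pca"))
  if (is.null(shared_cells))
    shared_cells <- intersect(rownames(sub$scores), rownames(ref$scores))
  miss <- setdiff(shared_cells, intersect(rownames(sub$scores),
                                          rownames(ref$scores)))
  if (length(miss)) stopf("cells absent from one of the PCAs: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  if (length(shared_cells) < 3) stopf("need at least 3 shared cells")
  ks <- min(n_top, ncol(sub$scores)); kr <- min(n_top, ncol(ref$scores))
  abs(stats::cor(sub$scores[shared_cells, seq_len(ks), drop = FALSE],
                 ref$scores[shared_cells, seq_len(kr), drop = FALSE]))
}
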