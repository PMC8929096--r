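# Simplified pseudotime over two selected cell types: k-means
# micro-clusters in PC space, a minimum spanning tree over their
# centroids, graph distance from a root plus an edge-projection offset.
# A deliberately deterministic, testable alternative to tree-embedding
# methods; branch ids come from the MST components around the root.

#' Fit an MST pseudotime over two cell types
#'
#' Cells of the `types` pair (a source population and its derivative) are
#' partitioned into k-means micro-clusters in PC space; a minimum spanning
#' tree with Euclidean edge weights connects the centroids; the root is
#' the centroid with the highest fraction of `root_type` cells; a cell's
#' pseudotime is the tree distance from the root to its centroid, adjusted
#' by the cell's projection offset along the nearest incident tree edge,
#' then shifted so the minimum is 0.
#'
#' The fit is flagged `degenerate` when fewer than `min_cells_per_micro`
#' cells per micro-cluster are available (the centroid geometry is then
#' unstable); in that case the number of micro-clusters is reduced to
#' `floor(n / min_cells_per_micro)` before fitting.
#'
#' @param scores an `sc_pca` or cells x dims matrix with cell-ID rownames.
#' @param labels named per-cell type labels covering the score rows.
#' @param types length-2 character vector: the two types to include.
#' @param root_type type anchoring pseudotime 0 (default `types[1]`); each
#'   of `types` must have at least 20 cells.
#' @param n_micro number of k-means micro-clusters (default 30).
#' @param dims leading PC dimensions used (default 30).
#' @param min_cells_per_micro stability threshold (default 10).
#' @param seed integer seed for k-means.
#' @return an object of class `trajectory_result`: `cells`, `pseudotime`
#'   (named, >= 0, 0 at the root-nearest cell), `state` (branch id, 0 =
#'   root component), `micro` (cell -> centroid), `centroids`, `mst_edges`
#'   (data.frame from, to, weight), `root`, `degenerate`.
#' @export
fit_trajectory <- function(scores, labels, types, root_type = types[1],
                           n_micro = 30, dims = 30,
                           min_cells_per_micro = 10, seed = 0) {
  if (inherits(scores, "sc_pca")) scores <- scores$scores
  if (length(types) != 2) stopf("types must name exactly two cell types")
  labels <- labels[intersect(names(labels), rownames(scores))]
  cells <- names(labels)[labels %in% types]
  for (ty in types)
    if (sum(labels[cells] == ty) < 20)
      stopf("type '%s' has %d cells in the sample (need >= 20)",
            ty, sum(labels[cells] == ty))
  X <- scores[cells, seq_len(min(dims, ncol(scores))), drop = FALSE]
  n <- nrow(X)
  degenerate <- n < min_cells_per_micro * n_micro
  k <- max(2L, min(n_micro, floor(n / min_cells_per_micro)))
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 5,
                                      iter.max = 100))
  centers <- km$centers
  D <- as.matrix(stats::dist(centers))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  root_frac <- vapply(seq_len(k), function(j)
    mean(labels[cells][km$cluster == j] == root_type), numeric(1))
  alld <- igraph::distances(mst)
  cand <- which(root_frac > max(root_frac) - 1e-9)
  # ties (several centroids pure in the root type) resolve to the tree
  # terminus: the candidate with the largest MST eccentricity, so the
  # root sits at an end of the path rather than mid-way through it
  root <- cand[which.max(apply(alld[cand, , drop = FALSE], 1, max))]
  ddist <- alld[root, ]
  el <- igraph::as_edgelist(mst, names = FALSE)

  pt <- numeric(n)
  for (j in seq_len(k)) {
    cl_cells <- which(km$cluster == j)
    if (!length(cl_cells)) next
    nbrs <- unique(c(el[el[, 1] == j, 2], el[el[, 2] == j, 1]))
    if (!length(nbrs)) { pt[cl_cells] <- ddist[j]; next }
    V <- sweep(X[cl_cells, , drop = FALSE], 2, centers[j, ])
    best_d2 <- rep(Inf, length(cl_cells))
    best_off <- numeric(length(cl_cells))
    best_nb <- integer(length(cl_cells))
    for (nb in nbrs) {
      e <- centers[nb, ] - centers[j, ]
      len <- sqrt(sum(e^2))
      t_raw <- as.numeric(V %*% (e / len))
      t_cl <- pmin(pmax(t_raw, 0), len)
      d2 <- rowSums(V^2) - 2 * t_cl * t_raw + t_cl^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_off[upd] <- t_cl[upd]
      best_nb[upd] <- nb
    }
    downstream <- ddist[best_nb] > ddist[j]
    pt[cl_cells] <- ddist[j] + ifelse(downstream, best_off, -best_off)
  }
  pt <- pt - min(pt)
  names(pt) <- cells

  comp <- igraph::components(igraph::delete_vertices(mst, root))$membership
  state_of_centroid <- integer(k)
  state_of_centroid[-root] <- comp
  state <- state_of_centroid[km$cluster]
  names(state) <- cells

  structure(
    list(cells = cells, pseudotime = pt, state = state,
         micro = stats::setNames(km$cluster, cells), centroids = centers,
         mst_edges = data.frame(from = el[, 1], to = el[, 2],
                                weight = igraph::E(mst)$weight),
         root = root, degenerate = degenerate),
    class = "trajectory_result")
}

#' Trajectory recipe for one (sub)sample
#'
#' The package's standard pseudotime recipe: subset the normalised matrix
#' to the two trajectory types, re-select HVGs on the subset, run a
#' depth-regressed PCA (the residual library-size axis otherwise competes
#' with the differentiation axis), choose the trajectory dimensionality by
#' the scree elbow (a one-dimensional continuum needs few components; the
#' remaining PCs contribute only noise to centroid distances), and fit the
#' MST pseudotime.
#'
#' @param nm an `sc_norm` (any cell set; will be subset).
#' @param labels named per-cell type labels.
#' @param types length-2 vector `(source, sink)`.
#' @param n_hvg HVGs for the subset PCA (default 2000, capped).
#' @param n_pcs components computed before elbow selection (default 30).
#' @param seed integer seed.
#' @param ... passed to [fit_trajectory()].
#' @return a `trajectory_result` (see [fit_trajectory()]).
#' @export
fit_sample_trajectory <- function(nm, labels, types, n_hvg = 2000,
                                  n_pcs = 30, seed = 0, ...) {
  stopifnot(inherits(nm, "sc_norm"))
  labels <- labels[intersect(names(labels), colnames(nm$values))]
  cells <- names(labels)[labels %in% types]
  if (length(cells) < 40)
    stopf("only %d cells of types %s/%s in the sample", length(cells),
          types[1], types[2])
  sub <- subset_norm(nm, cells)
  sub <- select_hvg(sub, min(n_hvg, nrow(sub$values)))
  batch <- if (!is.null(sub$meta) && "batch" %in% colnames(sub$meta))
    sub$meta$batch
  pca <- run_pca(sub, n_pcs = min(n_pcs, length(cells) - 1),
                 batch = batch, regress_depth = TRUE)
  dims <- max(2L, as.integer(elbow_point(pca)))
  fit_trajectory(pca, labels, types, dims = dims, seed = seed, ...)
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %d cells, %d micro-clusters, root %d%s\n",
              length(x$cells), nrow(x$centroids), x$root,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Per-type density over the pseudotime axis
#'
#' Kernel density of each type's cells on a common pseudotime grid,
#' renormalised to integrate to 1 on the grid. Types with fewer than 5
#' cells are omitted with a warning; a fit whose pseudotime collapses to a
#' point is flagged as a degenerate spike.
#'
#' @param tr a `trajectory_result`.
#' @param labels named per-cell type labels.
#' @param n_grid grid resolution (default 512).
#' @return list with `grid`, `density` (types x grid matrix, possibly with
#'   zero rows), and `spike` flag.
#' @export
pseudotime_density <- function(tr, labels, n_grid = 512) {
  stopifnot(inherits(tr, "trajectory_result"))
  pt <- tr$pseudotime
  labels <- labels[names(pt)]
  rng <- range(pt)
  spike <- diff(rng) < 1e-8
  grid <- seq(rng[1], if (spike) rng[1] + 1 else rng[2], length.out = n_grid)
  types <- unique(labels)
  dens <- matrix(0, 0, n_grid)
  kept <- character(0)
  if (!spike) {
    for (ty in types) {
      v <- pt[labels == ty]
      if (length(v) < 5) {
        warnf("type '%s' has %d cells with pseudotime; density omitted",
              ty, length(v))
        next
      }
      d <- stats::density(v, from = grid[1], to = grid[n_grid], n = n_grid)
      y <- d$y / sum((d$y[-1] + d$y[-n_grid]) / 2 * diff(grid))
      dens <- rbind(dens, y)
      kept <- c(kept, ty)
    }
    rownames(dens) <- kept
  } else {
    warnf("all pseudotimes identical: degenerate spike")
  }
  list(grid = grid, density = dens, spike = spike)
}

#' Trajectory-dependent differential expression
#'
#' Per gene, a Gaussian likelihood-ratio test of a natural cubic spline of
#' pseudotime (`df` degrees of freedom) against an intercept-only model,
#' on log-normalised values, BH-adjusted. The Gaussian working model on
#' the log layer is used because the trajectory consumes the already
#' normalised data without re-standardisation.
#'
#' @param nm an `sc_norm`.
#' @param tr a `trajectory_result` (>= 50 cells with pseudotime).
#' @param df spline degrees of freedom (default 3; must be below the
#'   number of distinct pseudotime values).
#' @param q_cutoff DEG cutoff on BH-adjusted p (default 0.01).
#' @param chunk genes per dense block.
#' @return list with `table` (gene, stat, p_value, q_value), `genes` (the
#'   DEGs), `n` (DEG count).
#' @export
trajectory_deg <- function(nm, tr, df = 3, q_cutoff = 0.01, chunk = 500) {
  stopifnot(inherits(nm, "sc_norm"), inherits(tr, "trajectory_result"))
  cells <- intersect(names(tr$pseudotime), colnames(nm$values))
  if (length(cells) < 50)
    stopf("need >= 50 cells with pseudotime, got %d", length(cells))
  pt <- tr$pseudotime[cells]
  if (df >= length(unique(pt)))
    stopf("df (%d) must be below the number of distinct pseudotime values (%d)",
          df, length(unique(pt)))
  X <- cbind(1, splines::ns(pt, df = df))
  qrX <- qr(X)
  n <- length(cells)
  genes <- rownames(nm$values)
  stat <- numeric(length(genes))
  for (start in seq(1, length(genes), by = chunk)) {
    gi <- start:min(start + chunk - 1, length(genes))
    Y <- t(as.matrix(nm$values[gi, cells, drop = FALSE]))
    rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
    rss1 <- colSums(qr.resid(qrX, Y)^2)
    s <- n * log(rss0 / rss1)
    s[rss0 == 0] <- 0
    s[rss1 == 0 & rss0 > 0] <- Inf
    stat[gi] <- s
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = genes, stat = stat, p_value = p, q_value = q,
                    row.names = NULL)
  deg <- genes[q < q_cutoff]
  list(table = tab, genes = deg, n = length(deg))
}
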