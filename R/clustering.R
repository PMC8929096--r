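# SNN-graph community clustering and the five pair-counting agreement
# indices (RI, MA, HA, FM, JI) used to compare subsample clusterings with
# the full-pool reference.

#' Shared-nearest-neighbour graph in PC space
#'
#' k-nearest neighbours by Euclidean distance in PC space (neighbour sets
#' include the cell itself), re-weighted by the Jaccard overlap of
#' neighbour sets; edges with weight below `prune` are removed.
#'
#' @param scores an `sc_pca` or a cells x dims score matrix with cell-ID
#'   rownames.
#' @param k_neighbors neighbours per cell (`< n_cells`), default 20.
#' @param prune Jaccard pruning threshold, default 1/15.
#' @param dims number of leading dimensions to use (default up to 30).
#' @return an undirected weighted `igraph` graph whose vertex names are the
#'   cell IDs (isolated cells are kept as vertices).
#' @export
build_snn <- function(scores, k_neighbors = 20, prune = 1 / 15, dims = 30) {
  if (inherits(scores, "sc_pca")) scores <- scores$scores
  n <- nrow(scores)
  if (k_neighbors >= n)
    stopf("k_neighbors (%d) must be < number of cells (%d)", k_neighbors, n)
  X <- scores[, seq_len(min(dims, ncol(scores))), drop = FALSE]
  k <- k_neighbors
  nn <- RANN::nn2(X, k = k)$nn.idx
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn), x = 1,
                            dims = c(n, n))
  ov <- Matrix::tcrossprod(N)                 # |knn(i) intersect knn(j)|
  rm(N)
  # each undirected pair once: upper triangle only
  ov <- methods::as(Matrix::triu(ov, k = 1), "TsparseMatrix")
  w <- ov@x / (2 * k - ov@x)                  # Jaccard of the two k-sets
  keep <- w >= prune
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ov@i[keep] + 1L, ov@j[keep] + 1L),
                         weight = w[keep])
  igraph::set_vertex_attr(g, "name", value = rownames(scores))
}

#' Louvain community clustering of an SNN graph
#'
#' Modularity optimisation (multilevel/Louvain) with a resolution
#' parameter. Deterministic given the seed; vertices in singleton
#' components become their own clusters. Cluster IDs are dense from 0,
#' ordered by decreasing size.
#'
#' @param graph an `igraph` graph with cell-ID vertex names.
#' @param resolution positive resolution parameter (default 1.0).
#' @param seed integer seed.
#' @param n_pcs_used recorded for provenance only.
#' @return an object of class `sc_clusters`: `assignment` (named integer
#'   vector, cell -> cluster in `0:(n_clusters-1)`), `resolution`,
#'   `n_clusters`, `n_pcs_used`.
#' @export
cluster_graph <- function(graph, resolution = 1.0, seed = 0,
                          n_pcs_used = NA_integer_) {
  if (igraph::vcount(graph) == 0) stopf("empty graph")
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(graph,
                                               resolution = resolution)))
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  assignment <- unname(relab[as.character(memb)])
  names(assignment) <- igraph::V(graph)$name
  structure(
    list(assignment = assignment, resolution = resolution,
         n_clusters = length(sizes), n_pcs_used = n_pcs_used),
    class = "sc_clusters")
}

#' @export
print.sc_clusters <- function(x, ...) {
  cat(sprintf("<sc_clusters> %d cells in %d clusters (resolution %g)\n",
              length(x$assignment), x$n_clusters, x$resolution))
  invisible(x)
}

as_assignment <- function(x) {
  if (inherits(x, "sc_clusters")) x$assignment else x
}

#' Pair-count table of two partitions
#'
#' Counts, over all unordered cell pairs, how many are co-clustered in
#' both partitions (`a`), only in the first (`b`), only in the second
#' (`c`), or in neither (`d`), computed from the contingency table in
#' O(cells + table) time.
#'
#' @param A,B `sc_clusters` or label vectors over the same cells. Named
#'   vectors are aligned by cell ID; a cell-set mismatch is an error that
#'   lists the symmetric difference.
#' @return an object of class `pair_counts`: `a`, `b`, `c`, `d`, `n`, with
#'   `a + b + c + d = n(n-1)/2`.
#' @export
pair_counts <- function(A, B) {
  a_lab <- as_assignment(A); b_lab <- as_assignment(B)
  if (!is.null(names(a_lab)) && !is.null(names(b_lab))) {
    only_a <- setdiff(names(a_lab), names(b_lab))
    only_b <- setdiff(names(b_lab), names(a_lab))
    if (length(only_a) || length(only_b))
      stopf("cell sets differ; only in A: {%s}, only in B: {%s}",
            paste(utils::head(only_a, 5), collapse = ","),
            paste(utils::head(only_b, 5), collapse = ","))
    b_lab <- b_lab[names(a_lab)]
  } else if (length(a_lab) != length(b_lab)) {
    stopf("partitions have different lengths (%d vs %d)",
          length(a_lab), length(b_lab))
  }
  n <- length(a_lab)
  tab <- table(factor(a_lab), factor(b_lab))
  a <- sum(ch2(as.numeric(tab)))
  b <- sum(ch2(as.numeric(rowSums(tab)))) - a
  cc <- sum(ch2(as.numeric(colSums(tab)))) - a
  d <- ch2(n) - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, n = n), class = "pair_counts")
}

#' The five pair-counting agreement indices
#'
#' From one pair-count table computes:
#' \describe{
#'   \item{RI}{Rand index `(a+d)/C(n,2)`.}
#'   \item{MA}{Morey-Agresti adjusted Rand:
#'     `(S - E) / ((Sr + Sc)/2 - E)` with `S = sum(nij^2)`,
#'     `Sr = sum(ni.^2)`, `Sc = sum(n.j^2)` and the chance term
#'     `E = Sr * Sc / n^2` (the Morey-Agresti approximation of
#'     `E[sum(nij^2)]`).}
#'   \item{HA}{Hubert-Arabie adjusted Rand
#'     `(C(n,2)(a+d) - Q) / (C(n,2)^2 - Q)` with
#'     `Q = (a+b)(a+c) + (c+d)(b+d)`.}
#'   \item{FM}{Fowlkes-Mallows `a / sqrt((a+b)(a+c))`, the geometric mean
#'     of pairwise precision and recall.}
#'   \item{JI}{Jaccard `a / (a+b+c)`.}
#' }
#' Undefined-denominator cases return documented limits, never NaN: FM is 0
#' when either partition has no co-clustered pair; JI is 1 when
#' `a+b+c = 0`; HA and MA are 1 when their chance-corrected denominator
#' vanishes (which only happens for identical trivial partitions).
#'
#' @param pc a `pair_counts` (n >= 2).
#' @return an object of class `agreement_scores` with fields `RI`, `MA`,
#'   `HA`, `FM`, `JI`.
#' @export
agreement_indices <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  a <- pc$a; b <- pc$b; cc <- pc$c; d <- pc$d; n <- pc$n
  if (n < 2) stopf("need at least 2 cells")
  tot <- ch2(n)
  RI <- (a + d) / tot
  FM <- if ((a + b) == 0 || (a + cc) == 0) 0 else a / sqrt((a + b) * (a + cc))
  JI <- if ((a + b + cc) == 0) 1 else a / (a + b + cc)
  Q <- (a + b) * (a + cc) + (cc + d) * (b + d)
  ha_den <- tot^2 - Q
  HA <- if (ha_den == 0) 1 else (tot * (a + d) - Q) / ha_den
  S <- 2 * a + n; Sr <- 2 * (a + b) + n; Sc <- 2 * (a + cc) + n
  E <- Sr * Sc / n^2
  ma_den <- (Sr + Sc) / 2 - E
  MA <- if (abs(ma_den) < 1e-12) 1 else (S - E) / ma_den
  structure(list(RI = RI, MA = MA, HA = HA, FM = FM, JI = JI),
            class = "agreement_scores")
}

#' @export
print.agreement_scores <- function(x, ...) {
  cat(sprintf("RI %.4f  MA %.4f  HA %.4f  FM %.4f  JI %.4f\n",
              x$RI, x$MA, x$HA, x$FM, x$JI))
  invisible(x)
}

#' Agreement between two partitions
#'
#' Convenience wrapper: [pair_counts()] followed by [agreement_indices()].
#'
#' @inheritParams pair_counts
#' @return an `agreement_scores`.
#' @export
compare_partitions <- function(A, B) agreement_indices(pair_counts(A, B))

#' Compare a subsample clustering with the full-pool reference
#'
#' Restricts the reference labels to the subsample's cells, then computes
#' the pair-count agreement indices.
#'
#' @param sub_labels clustering of the subsample (`sc_clusters` or named
#'   vector).
#' @param ref_labels clustering of the pool; must cover all subsample
#'   cells.
#' @return an `agreement_scores`.
#' @export
compare_to_reference <- function(sub_labels, ref_labels) {
  s <- as_assignment(sub_labels); r <- as_assignment(ref_labels)
  if (is.null(names(s)) || is.null(names(r)))
    stopf("labels must be named by cell ID")
  miss <- setdiff(names(s), names(r))
  if (length(miss) == length(s)) stopf("no subsample cell appears in the reference")
  if (length(miss))
    stopf("subsample cells missing from reference: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  compare_partitions(s, r[names(s)])
}
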