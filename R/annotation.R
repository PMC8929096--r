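# Assigning clusters to cell types: marker-set scores, Spearman
# correlation with bulk reference profiles, per-cell ICI (index of cell
# identity) scores with bootstrap significance, and the discovered-type
# accounting across ladder sizes.

cluster_means <- function(values, labels) {
  labels <- as_assignment(labels)
  cells <- intersect(colnames(values), names(labels))
  if (!length(cells)) stopf("no overlap between matrix cells and labels")
  labels <- labels[cells]
  f <- factor(labels)
  ind <- Matrix::sparseMatrix(i = seq_along(cells), j = as.integer(f), x = 1,
                              dims = c(length(cells), nlevels(f)))
  sums <- as.matrix(values[, cells, drop = FALSE] %*% ind)
  colnames(sums) <- levels(f)
  list(means = sweep(sums, 2, as.numeric(table(f)), `/`),
       sums = sums, sizes = as.numeric(table(f)), cells = cells)
}

# 10% relative margin rule shared by cluster- and cell-level assignment:
# the top score must be positive and exceed the runner-up by the margin,
# otherwise "unassigned" (prevents arbitrary ties).
top_with_margin <- function(score_row, margin = 0.1) {
  o <- order(score_row, decreasing = TRUE)
  top <- score_row[o[1]]
  runner <- if (length(score_row) > 1) score_row[o[2]] else -Inf
  if (top > 0 && (runner <= 0 || top >= (1 + margin) * runner))
    names(score_row)[o[1]] else "unassigned"
}

#' Marker-based cluster-to-type scores and assignment
#'
#' `score(cluster, type)` is the mean, over the type's marker genes, of the
#' difference between mean log-normalised expression in the cluster and in
#' all other cells. A cluster is assigned the argmax type when the top
#' score is positive and clears a 10% relative margin over the runner-up;
#' otherwise it is left unassigned. Assignment is not injective: several
#' clusters may map to one type.
#'
#' @param nm an `sc_norm`.
#' @param labels an `sc_clusters` or named cluster vector.
#' @param markers named list, type -> character vector of marker genes (at
#'   least one marker of some type must be present in the data).
#' @param margin relative assignment margin (default 0.1).
#' @return list with `scores` (clusters x types), `assignment` (named
#'   character, cluster -> type or "unassigned").
#' @export
marker_score <- function(nm, labels, markers, margin = 0.1) {
  stopifnot(inherits(nm, "sc_norm"))
  genes <- rownames(nm$values)
  present <- lapply(markers, intersect, genes)
  if (all(lengths(present) == 0))
    stopf("no marker genes found in data; missing e.g.: %s",
          paste(utils::head(unlist(markers), 5), collapse = ", "))
  cm <- cluster_means(nm$values, labels)
  tot <- Matrix::rowSums(nm$values[, cm$cells, drop = FALSE])
  n <- length(cm$cells)
  other <- sweep(-cm$sums, 1, tot, `+`) /
    matrix(n - cm$sizes, nrow(cm$sums), length(cm$sizes), byrow = TRUE)
  diff <- cm$means - other
  scores <- matrix(NA_real_, ncol(cm$means), length(markers),
                   dimnames = list(colnames(cm$means), names(markers)))
  for (ty in names(markers)) {
    mk <- present[[ty]]
    scores[, ty] <- if (length(mk)) colMeans(diff[mk, , drop = FALSE]) else 0
  }
  assignment <- apply(scores, 1, top_with_margin, margin = margin)
  list(scores = scores, assignment = assignment)
}

#' Spearman correlation of cluster profiles with bulk references
#'
#' Correlates each cluster's mean log-normalised profile with each column
#' of a bulk reference matrix over their shared genes.
#'
#' @param nm an `sc_norm`.
#' @param labels an `sc_clusters` or named cluster vector.
#' @param bulk_profiles genes x types numeric matrix with rownames.
#' @return clusters x types matrix of Spearman correlations, with a
#'   `assignment` attribute (argmax per cluster).
#' @export
bulk_spearman <- function(nm, labels, bulk_profiles) {
  stopifnot(inherits(nm, "sc_norm"))
  shared <- intersect(rownames(nm$values), rownames(bulk_profiles))
  if (length(shared) < 10)
    stopf("only %d genes shared with the bulk reference (need >= 10)",
          length(shared))
  cm <- cluster_means(nm$values, labels)
  rho <- stats::cor(cm$means[shared, , drop = FALSE],
                    as.matrix(bulk_profiles)[shared, , drop = FALSE],
                    method = "spearman")
  attr(rho, "assignment") <-
    stats::setNames(colnames(rho)[apply(rho, 1, which.max)], rownames(rho))
  rho
}

#' ICI (index of cell identity) scores with bootstrap significance
#'
#' For each cell and type, the specificity-weighted sum of marker
#' expression, multiplied by the fraction of the type's markers detected
#' in the cell, then normalised so each cell's scores sum to 1 across
#' types. Significance comes from a bootstrap null: `n_boot` resamples
#' (with replacement, from the full gene universe) of each type's marker
#' set, scored identically; the empirical p-value is the fraction of null
#' scores at least as large as the observed one, Benjamini-Hochberg
#' adjusted across all (cell, type) pairs. A cell is assigned its max-ICI
#' type when the adjusted p-value is below `p_threshold` and the score
#' clears a 10% relative margin; a type with no detected marker in a cell
#' scores 0 by construction.
#'
#' @param nm an `sc_norm`.
#' @param spec_table data frame with columns `gene`, `type`, `weight`
#'   (nonnegative specificity weights).
#' @param n_boot bootstrap iterations (>= 100; default 1000).
#' @param seed integer seed.
#' @param p_threshold adjusted-p threshold for assignment (default 0.05).
#' @param margin relative assignment margin (default 0.1).
#' @return list with `ici` (cells x types, rows summing to 1 for cells
#'   with any detected marker), `p`, `padj` (same shape), `assignment`
#'   (named character per cell).
#' @export
ici_assign <- function(nm, spec_table, n_boot = 1000, seed = 1234,
                       p_threshold = 0.05, margin = 0.1) {
  stopifnot(inherits(nm, "sc_norm"))
  spec_table <- as.data.frame(spec_table)
  if (!all(c("gene", "type", "weight") %in% colnames(spec_table)))
    stopf("spec_table needs columns gene, type, weight")
  if (nrow(spec_table) == 0) stopf("empty specificity table")
  if (any(spec_table$weight < 0)) stopf("specificity weights must be >= 0")
  E <- nm$values
  genes <- rownames(E); n <- ncol(E)
  types <- unique(spec_table$type)
  raw <- det <- matrix(0, n, length(types),
                       dimnames = list(colnames(E), types))
  null_ge <- matrix(0, n, length(types), dimnames = dimnames(raw))
  for (k in seq_along(types)) {
    st <- spec_table[spec_table$type == types[k] &
                     spec_table$gene %in% genes, , drop = FALSE]
    if (nrow(st) == 0) next
    gi <- match(st$gene, genes)
    w <- st$weight
    raw[, k] <- as.numeric(Matrix::crossprod(E[gi, , drop = FALSE], w))
    det[, k] <- Matrix::colMeans(E[gi, , drop = FALSE] > 0)
    m <- length(gi)
    boot_idx <- with_seed(derive_seed(seed, k),
                          sample.int(length(genes), m * n_boot, replace = TRUE))
    S <- Matrix::sparseMatrix(i = boot_idx,
                              j = rep(seq_len(n_boot), each = m),
                              x = rep(w, n_boot),
                              dims = c(length(genes), n_boot))
    null_k <- Matrix::crossprod(E, S)          # cells x n_boot
    null_ge[, k] <- Matrix::rowSums(null_k >= raw[, k])
  }
  weighted <- raw * det
  rs <- rowSums(weighted)
  ici <- weighted / ifelse(rs > 0, rs, 1)
  p <- (1 + null_ge) / (1 + n_boot)
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p),
                 dimnames = dimnames(p))
  assignment <- vapply(seq_len(n), function(i) {
    if (rs[i] == 0) return("unassigned")
    ty <- top_with_margin(ici[i, ], margin = margin)
    if (ty != "unassigned" && padj[i, ty] >= p_threshold) "unassigned" else ty
  }, character(1))
  names(assignment) <- colnames(E)
  list(ici = ici, p = p, padj = padj, assignment = assignment)
}

#' Cell types discovered at each ladder size
#'
#' A type counts as discovered at a size if at least one cluster (or cell)
#' was assigned to it at that size.
#'
#' @param annotations_by_size named list (names = sizes) whose elements are
#'   assignment vectors (cluster or cell -> type) or results of
#'   [marker_score()] / [ici_assign()].
#' @return list with `counts` (data.frame size, n_types), `sets` (types
#'   per size) and `first_discovery` (named vector, type -> smallest size
#'   at which it appears).
#' @export
types_discovered <- function(annotations_by_size) {
  sets <- lapply(annotations_by_size, function(x) {
    if (is.list(x) && !is.null(x$assignment)) x <- x$assignment
    setdiff(unique(unname(x)), "unassigned")
  })
  sizes <- as.integer(names(annotations_by_size))
  o <- order(sizes)
  all_types <- unique(unlist(sets))
  first <- vapply(all_types, function(ty) {
    hit <- sizes[o][vapply(sets[o], function(s) ty %in% s, logical(1))]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  list(counts = data.frame(size = sizes[o],
                           n_types = lengths(sets)[o],
                           row.names = NULL),
       sets = sets[o],
       first_discovery = first)
}
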