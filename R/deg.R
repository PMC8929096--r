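# One-vs-rest differential expression with detection-fraction and
# fold-change prefilters, Wilcoxon rank-sum testing, ROC classification
# power, and the DEG-recovery analysis across the subsampling ladder.

# Wilcoxon rank-sum machinery shared by find_markers() and roc_power():
# given per-gene midranks, group rank sums give both the normal-
# approximation p-value (tie-corrected, continuity-corrected, matching
# stats::wilcox.test(exact = FALSE, correct = TRUE)) and the AUC through
# the identity AUC = (R1 - n1(n1+1)/2) / (n1 n2).
rank_sum_test <- function(R1, n1, n2, tie_term) {
  U <- R1 - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  n <- n1 + n2
  z0 <- U - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1))))
  z <- (z0 - sign(z0) * 0.5) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma == 0] <- 1                      # fully tied: no evidence
  auc[!is.finite(auc)] <- 0.5
  list(p = pmin(p, 1), auc = auc)
}

# Per-gene midrank sums by group plus tie terms, accumulated gene by gene
# so no genes x cells rank matrix is ever held.
row_rank_stats <- function(V, group_idx, n_groups) {
  ng <- nrow(V)
  Rsums <- matrix(0, ng, n_groups)
  tie_term <- numeric(ng)
  for (i in seq_len(ng)) {
    x <- V[i, ]
    r <- rank(x)
    s <- rowsum(r, group_idx)
    Rsums[i, as.integer(rownames(s))] <- s[, 1]
    tl <- rle(sort.int(x, method = "quick"))$lengths
    tie_term[i] <- sum(tl^3 - tl)
  }
  list(Rsums = Rsums, tie_term = tie_term)
}

#' One-vs-rest marker detection
#'
#' For every group (cluster or annotated type) and gene, computes the
#' detection fractions inside (`pct_in`) and outside (`pct_out`) the
#' group and the natural-log fold-change
#' `ln((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`. Genes pass the
#' prefilter when `max(pct_in, pct_out) >= min_pct` and (with
#' `only_pos = TRUE`) `log_fc >= logfc_threshold` (otherwise
#' `|log_fc| >= logfc_threshold`). Surviving genes are tested by a
#' two-sided Wilcoxon rank-sum on the log-normalised values against all
#' other cells, BH-adjusted per group across tested genes. The table also
#' carries the gene's AUC as a single-feature classifier of group
#' membership and the classification power `2 * |AUC - 0.5|`.
#'
#' @param nm an `sc_norm`.
#' @param labels an `sc_clusters` or named group vector (>= 2 groups).
#'   Groups with fewer than 3 cells are skipped and recorded in the
#'   `skipped` attribute.
#' @param only_pos test up-regulated genes only (default TRUE).
#' @param min_pct minimum detection fraction (default 0.25).
#' @param logfc_threshold natural-log fold-change prefilter (default 0.25).
#' @return a `data.frame` (class `deg_table`) with columns `gene`, `group`,
#'   `log_fc`, `pct_in`, `pct_out`, `p_value`, `q_value`, `auc`, `power`.
#' @export
find_markers <- function(nm, labels, only_pos = TRUE, min_pct = 0.25,
                         logfc_threshold = 0.25) {
  stopifnot(inherits(nm, "sc_norm"))
  if (min_pct < 0 || min_pct > 1) stopf("min_pct must be in [0, 1]")
  labels <- as_assignment(labels)
  cells <- intersect(colnames(nm$values), names(labels))
  labels <- labels[cells]
  V <- if (identical(cells, colnames(nm$values))) nm$values
       else nm$values[, cells, drop = FALSE]
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("need at least 2 groups")
  sizes <- table(f)
  skipped <- names(sizes)[sizes < 3]
  groups <- setdiff(levels(f), skipped)
  if (length(skipped))
    warnf("skipping groups with < 3 cells: %s", paste(skipped, collapse = ", "))
  n <- ncol(V)
  ind <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                              dims = c(n, nlevels(f)),
                              dimnames = list(NULL, levels(f)))
  # stored entries of the log layer are exactly the detected counts, so
  # detection counts and expm1 sums come from @x alone (no matrix copies)
  W <- V
  W@x <- rep(1, length(V@x))
  det <- as.matrix(W %*% ind)
  W@x <- expm1(V@x)
  esum <- as.matrix(W %*% ind)
  rm(W)
  tot_det <- rowSums(det); tot_e <- rowSums(esum)
  nsz <- as.numeric(sizes)[match(colnames(ind), names(sizes))]

  per_group <- vector("list", length(groups)); names(per_group) <- groups
  for (gname in groups) {
    n1 <- sizes[[gname]]
    pct_in <- det[, gname] / n1
    pct_out <- (tot_det - det[, gname]) / (n - n1)
    m_in <- esum[, gname] / n1
    m_out <- (tot_e - esum[, gname]) / (n - n1)
    lfc <- log((m_in + 1) / (m_out + 1))
    pass <- pmax(pct_in, pct_out) >= min_pct &
      (if (only_pos) lfc >= logfc_threshold else abs(lfc) >= logfc_threshold)
    if (!any(pass)) next
    per_group[[gname]] <- data.frame(
      gene = rownames(V)[pass], group = gname,
      log_fc = lfc[pass], pct_in = pct_in[pass], pct_out = pct_out[pass],
      stringsAsFactors = FALSE)
  }
  tested_genes <- unique(unlist(lapply(per_group, `[[`, "gene")))
  out <- NULL
  if (length(tested_genes)) {
    Vd <- as.matrix(V[tested_genes, , drop = FALSE])
    rs <- row_rank_stats(Vd, as.integer(f), nlevels(f))
    rm(Vd)
    Rsums <- rs$Rsums
    dimnames(Rsums) <- list(tested_genes, levels(f))
    out <- do.call(rbind, lapply(groups, function(gname) {
      tab <- per_group[[gname]]
      if (is.null(tab)) return(NULL)
      gi <- match(tab$gene, tested_genes)
      n1 <- sizes[[gname]]
      wt <- rank_sum_test(Rsums[gi, gname], n1, n - n1, rs$tie_term[gi])
      tab$p_value <- wt$p
      tab$q_value <- stats::p.adjust(wt$p, method = "BH")
      tab$auc <- wt$auc
      tab$power <- 2 * abs(wt$auc - 0.5)
      tab
    }))
  }
  if (is.null(out))
    out <- data.frame(gene = character(), group = character(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_value = numeric(),
                      q_value = numeric(), auc = numeric(),
                      power = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("deg_table", "data.frame")
  out
}

#' ROC classification power of a single gene
#'
#' AUC of a gene as a one-feature classifier of group membership, via the
#' rank-sum identity `AUC = (R_in - n_in(n_in+1)/2) / (n_in * n_out)` with
#' midranks for ties (equivalently wins + half-ties over all
#' in-group/out-group pairs), and the classification power
#' `2 * |AUC - 0.5|`. A gene constant across all cells has AUC exactly
#' 0.5.
#'
#' @param nm an `sc_norm`, or `NULL` when `x_in`/`x_out` are given.
#' @param labels named group vector (used with `nm`).
#' @param gene gene ID.
#' @param group group whose cells form the positive class.
#' @param x_in,x_out alternatively, raw value vectors for the two classes.
#' @return list with `auc` and `power`.
#' @export
roc_power <- function(nm = NULL, labels = NULL, gene = NULL, group = NULL,
                      x_in = NULL, x_out = NULL) {
  if (is.null(x_in)) {
    stopifnot(inherits(nm, "sc_norm"))
    labels <- as_assignment(labels)
    cells <- intersect(colnames(nm$values), names(labels))
    v <- as.numeric(nm$values[gene, cells])
    ing <- labels[cells] == group
    x_in <- v[ing]; x_out <- v[!ing]
  }
  if (!length(x_in) || !length(x_out)) stopf("both groups must be nonempty")
  x <- c(x_in, x_out)
  r <- rank(x)
  tl <- rle(sort.int(x, method = "quick"))$lengths
  res <- rank_sum_test(sum(r[seq_along(x_in)]), length(x_in), length(x_out),
                       sum(tl^3 - tl))
  list(auc = res$auc, power = 2 * abs(res$auc - 0.5))
}

#' DEG recovery across the subsampling ladder
#'
#' Builds the nonredundant DEG union over all sizes (keyed by gene x
#' group), the fraction of that union recovered at each size, the DEGs
#' unique to a single size, and the AUC distributions of DEGs common to
#' all sizes versus size-unique DEGs.
#'
#' @param deg_by_size named list (names = sizes) of [find_markers()]
#'   tables; rows with `q_value < q_cutoff` count as DEGs.
#' @param q_cutoff DEG significance cutoff (default 0.05, BH scale).
#' @param reference `"union"` (default; the nonredundant union over sizes)
#'   or `"largest"` (the largest size's set). Both recovered fractions are
#'   returned regardless.
#' @return an object of class `recovery_report`: data frame `summary`
#'   (size, n_deg, recovered_union, recovered_largest, n_unique), the
#'   `union_keys`, and numeric `auc_common` / `auc_unique` distributions.
#' @export
recovery_analysis <- function(deg_by_size, q_cutoff = 0.05,
                              reference = c("union", "largest")) {
  reference <- match.arg(reference)
  sizes <- as.integer(names(deg_by_size))
  o <- order(sizes)
  sets <- lapply(deg_by_size, function(tab) {
    tab <- tab[tab$q_value < q_cutoff, , drop = FALSE]
    stats::setNames(tab$auc, paste(tab$gene, tab$group, sep = "|"))
  })
  union_keys <- unique(unlist(lapply(sets, names)))
  if (!length(union_keys)) stopf("no DEGs at q < %g in any size", q_cutoff)
  largest_keys <- names(sets[[which.max(sizes)]])
  member <- vapply(sets, function(s) union_keys %in% names(s),
                   logical(length(union_keys)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  n_hits <- rowSums(member)
  common_keys <- union_keys[n_hits == length(sets)]
  unique_keys <- union_keys[n_hits == 1]
  summary <- data.frame(
    size = sizes[o],
    n_deg = vapply(sets[o], length, integer(1)),
    recovered_union = vapply(sets[o], function(s)
      mean(union_keys %in% names(s)), numeric(1)),
    recovered_largest = vapply(sets[o], function(s)
      if (length(largest_keys)) mean(largest_keys %in% names(s)) else NA_real_,
      numeric(1)),
    n_unique = vapply(seq_along(sets)[o], function(k)
      sum(member[, k] & n_hits == 1), integer(1)),
    row.names = NULL)
  biggest <- sets[[which.max(sizes)]]
  auc_common <- unname(biggest[common_keys[common_keys %in% names(biggest)]])
  auc_unique <- unlist(lapply(seq_along(sets), function(k) {
    keys <- union_keys[member[, k] & n_hits == 1]
    unname(sets[[k]][keys])
  }))
  structure(
    list(summary = summary, union_keys = union_keys,
         common_keys = common_keys, unique_keys = unique_keys,
         auc_common = auc_common, auc_unique = auc_unique,
         reference = reference),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d nonredundant DEGs over %d sizes (%d common, %d size-unique)\n",
              length(x$union_keys), nrow(x$summary),
              length(x$common_keys), length(x$unique_keys)))
  print(x$summary)
  invisible(x)
}
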