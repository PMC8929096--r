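# Synthetic count-matrix generator with known ground truth: discrete cell
# types with uneven proportions (including rare ones), type-specific marker
# genes, negative-binomial counts with log-normal depths, optional batch
# structure and an optional differentiation trajectory between two types.

#' Specification of a synthetic single-cell dataset
#'
#' Describes the generative model used by [generate_dataset()]: counts are
#' negative binomial with mean `s_c * m_g * f_{g,t(c)} * b_{g,batch(c)}`,
#' where `s_c` is a log-normal per-cell depth factor, `m_g` a log-normal
#' base mean, `f` the multiplicative marker fold-change (`exp(marker_logfc)`
#' for markers of the cell's type, 1 otherwise) and `b` a per-gene
#' log-normal batch factor. Variance follows the mean/dispersion
#' parameterisation `Var = mu + mu^2 * dispersion`. Dropout is implicit in
#' NB sampling at low means; no extra zero-inflation layer is added, so the
#' ground truth stays analytic.
#'
#' @param n_cells,n_genes positive counts.
#' @param type_names character vector of cell-type labels.
#' @param proportions nonnegative weights summing to 1 (within 1e-9), one
#'   per type.
#' @param markers_per_type number of marker genes planted per type
#'   (`markers_per_type * length(type_names)` must not exceed `n_genes`).
#' @param marker_logfc natural-log fold-change of a marker gene in its type.
#' @param base_mean_logparams `c(mu, sigma)` of the log-normal gene base
#'   means. Marker genes are planted in genes with base mean at or above
#'   the median, matching the expression level of curated identity
#'   markers.
#' @param dispersion NB dispersion (inverse size), scalar or per-gene.
#'   `0.3` is typical of droplet data. Values `<= 1e-12` switch to Poisson
#'   sampling.
#' @param libsize_logparams `c(mu, sigma)` of the log-normal per-cell depth
#'   factors.
#' @param n_batches number of batches; cells are assigned uniformly.
#' @param batch_logfc_sd SD of the per-gene, per-batch log-normal shift.
#' @param trajectory `NULL`, or `list(source=, sink=, n_stages=)` naming two
#'   types connected by a differentiation continuum. Trajectory cells get a
#'   true pseudotime `u` in `[0,1]` (uniform, or over `n_stages` discrete
#'   stages when given) and their marker fold-changes interpolate
#'   log-linearly from the source profile (`u = 0`) to the sink profile
#'   (`u = 1`). Labels split the continuum at the quantile implied by the
#'   two types' relative proportions, so marginal type frequencies are
#'   preserved.
#' @param seed integer seed; identical specs produce bit-identical data.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [root_pool_spec()]
#' @export
synthetic_spec <- function(n_cells = 5000,
                           n_genes = 3000,
                           type_names = paste0("type", 1:8),
                           proportions = c(0.25, 0.20, 0.15, 0.12, 0.10,
                                           0.08, 0.06, 0.04),
                           markers_per_type = 20,
                           marker_logfc = log(4),
                           base_mean_logparams = c(-1.8, 1.2),
                           dispersion = 0.3,
                           libsize_logparams = c(0, 0.35),
                           n_batches = 1,
                           batch_logfc_sd = 0,
                           trajectory = NULL,
                           seed = 1234) {
  K <- length(type_names)
  if (n_cells < 1 || n_genes < 1) stopf("n_cells and n_genes must be positive")
  if (length(proportions) != K)
    stopf("proportions must have one entry per type")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stopf("proportions must be nonnegative and sum to 1 (got sum %.12f)",
          sum(proportions))
  if (anyDuplicated(type_names)) stopf("duplicate type names")
  if (markers_per_type * K > n_genes)
    stopf("markers_per_type * n_types (%d) exceeds n_genes (%d)",
          markers_per_type * K, n_genes)
  if (!(length(dispersion) %in% c(1L, n_genes)) || any(dispersion < 0))
    stopf("dispersion must be a nonnegative scalar or per-gene vector")
  if (n_batches < 1) stopf("n_batches must be positive")
  if (!is.null(trajectory)) {
    trajectory <- as.list(trajectory)
    if (is.null(trajectory$source) || is.null(trajectory$sink))
      stopf("trajectory needs 'source' and 'sink' type names")
    if (!all(c(trajectory$source, trajectory$sink) %in% type_names))
      stopf("trajectory types must be members of type_names")
    if (trajectory$source == trajectory$sink)
      stopf("trajectory source and sink must differ")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         type_names = type_names, proportions = proportions,
         markers_per_type = as.integer(markers_per_type),
         marker_logfc = marker_logfc,
         base_mean_logparams = base_mean_logparams,
         dispersion = dispersion,
         libsize_logparams = libsize_logparams,
         n_batches = as.integer(n_batches),
         batch_logfc_sd = batch_logfc_sd,
         trajectory = trajectory,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Preset emulating an integrated Arabidopsis-root cell pool (synthetic)
#'
#' A fully synthetic stand-in for a large multi-study Arabidopsis root cell
#' pool: ten root cell types with uneven proportions including
#' quiescent-center cells at 0.3%, 50 identity markers per type at 10-fold
#' change (cell-identity markers are strong; droplet studies of this tissue
#' report hundreds of DE genes per type), five batches standing for five
#' source studies, and a meristem-to-hair-cell differentiation trajectory.
#'
#' @param n_cells,n_genes pool dimensions.
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
root_pool_spec <- function(n_cells = 50000, n_genes = 3000, seed = 1234) {
  synthetic_spec(
    n_cells = n_cells, n_genes = n_genes,
    type_names = c("hair", "nonhair", "cortex", "endodermis", "meristem",
                   "root_cap", "pericycle", "stele", "xylem",
                   "quiescent_center"),
    proportions = c(0.18, 0.15, 0.14, 0.12, 0.13,
                    0.10, 0.09, 0.06, 0.027, 0.003),
    markers_per_type = 50,
    marker_logfc = log(10),
    base_mean_logparams = c(-1.8, 1.2),
    dispersion = 0.3,
    libsize_logparams = c(0, 0.35),
    n_batches = 5,
    batch_logfc_sd = 0.15,
    trajectory = list(source = "meristem", sink = "hair"),
    seed = seed)
}

#' Generate a synthetic dataset with ground truth
#'
#' Samples counts from the model described in [synthetic_spec()]. The same
#' spec (including seed) always yields bit-identical output.
#'
#' @param spec a `synthetic_spec`.
#' @param chunk_cells cells per generation block (memory/speed trade-off;
#'   does not affect the result).
#' @return a list with elements:
#' \describe{
#'   \item{matrix}{an [sc_expression] with per-cell `batch` and
#'     `known_type` metadata;}
#'   \item{truth}{a list with `cell_type`, `pseudotime` (NA outside the
#'     trajectory), `batch` (all named by cell), and `marker_of`, a
#'     gene-named vector giving each marker gene's type (NA for
#'     non-markers);}
#'   \item{spec}{the input spec.}
#' }
#' @export
generate_dataset <- function(spec, chunk_cells = 2000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- length(spec$type_names)
  exp_rare <- spec$n_cells * min(spec$proportions)
  if (exp_rare < 1)
    warnf("rarest type has expected count %.2f (< 1 cell) at n_cells = %d",
          exp_rare, spec$n_cells)

  with_seed(spec$seed, {
    n <- spec$n_cells; g <- spec$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(g))
    cell_ids <- sprintf("cell%06d", seq_len(n))

    type <- sample(spec$type_names, n, replace = TRUE, prob = spec$proportions)
    batch <- if (spec$n_batches > 1)
      sample(sprintf("batch%d", seq_len(spec$n_batches)), n, replace = TRUE)
    else rep("batch1", n)

    m_g <- stats::rlnorm(g, spec$base_mean_logparams[1],
                         spec$base_mean_logparams[2])
    s_c <- stats::rlnorm(n, spec$libsize_logparams[1],
                         spec$libsize_logparams[2])

    # markers are planted in genes of at least median base expression:
    # curated identity markers are well-expressed genes, and a "marker"
    # with a vanishing mean would be undetectable by construction
    eligible <- which(m_g >= stats::median(m_g))
    n_mk <- spec$markers_per_type * K
    if (n_mk > length(eligible)) eligible <- seq_len(g)
    marker_idx <- sample(eligible, n_mk)
    # deal markers to types in snake order of base mean so every type's
    # marker set carries (near-)equal total base mass: types then differ
    # in composition, not in expected total RNA, and depth normalisation
    # leaves non-marker genes exactly null
    marker_of <- rep(NA_character_, g)
    o <- order(m_g[marker_idx], decreasing = TRUE)
    snake <- rep(c(seq_len(K), rev(seq_len(K))), length.out = n_mk)
    marker_of[marker_idx[o]] <- spec$type_names[snake]
    names(marker_of) <- gene_ids
    logF <- matrix(0, g, K, dimnames = list(NULL, spec$type_names))
    mk <- which(!is.na(marker_of))
    logF[cbind(mk, match(marker_of[mk], spec$type_names))] <- spec$marker_logfc

    logB <- matrix(0, g, spec$n_batches)
    if (spec$n_batches > 1 && spec$batch_logfc_sd > 0)
      logB[] <- stats::rnorm(g * spec$n_batches, 0, spec$batch_logfc_sd)

    pseudotime <- rep(NA_real_, n)
    if (!is.null(spec$trajectory)) {
      src <- spec$trajectory$source; snk <- spec$trajectory$sink
      traj <- which(type %in% c(src, snk))
      u <- stats::runif(length(traj))
      if (!is.null(spec$trajectory$n_stages)) {
        ns <- as.integer(spec$trajectory$n_stages)
        u <- (ceiling(u * ns) - 0.5) / ns   # discrete stage midpoints
      }
      p_src <- spec$proportions[match(src, spec$type_names)]
      p_snk <- spec$proportions[match(snk, spec$type_names)]
      tau <- p_src / (p_src + p_snk)
      type[traj] <- ifelse(u < tau, src, snk)
      pseudotime[traj] <- u
    }

    type_idx <- match(type, spec$type_names)
    batch_idx <- match(batch, sprintf("batch%d", seq_len(spec$n_batches)))
    size_nb <- 1 / pmax(spec$dispersion, 1e-300)
    poisson <- all(spec$dispersion <= 1e-12)

    ti <- tj <- tx <- vector("list", ceiling(n / chunk_cells))
    starts <- seq(1L, n, by = chunk_cells)
    for (ci in seq_along(starts)) {
      idx <- starts[ci]:min(starts[ci] + chunk_cells - 1L, n)
      nc <- length(idx)
      logf <- logF[, type_idx[idx], drop = FALSE]
      tr <- which(!is.na(pseudotime[idx]))
      if (length(tr)) {
        u <- pseudotime[idx][tr]
        logf[, tr] <- logF[, spec$trajectory$source] %o% (1 - u) +
          logF[, spec$trajectory$sink] %o% u
      }
      mu <- m_g * exp(logf + logB[, batch_idx[idx], drop = FALSE])
      mu <- mu * rep(s_c[idx], each = g)
      x <- if (poisson) stats::rpois(g * nc, lambda = mu)
           else stats::rnbinom(g * nc, mu = mu, size = size_nb)
      nz <- which(x > 0)
      ti[[ci]] <- ((nz - 1L) %% g) + 1L
      tj[[ci]] <- idx[1L] + ((nz - 1L) %/% g)
      tx[[ci]] <- x[nz]
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(ti), j = unlist(tj), x = as.numeric(unlist(tx)),
      dims = c(g, n), dimnames = list(gene_ids, cell_ids))

    names(type) <- names(batch) <- names(pseudotime) <- cell_ids
    mat <- sc_expression(counts,
                         meta = data.frame(batch = batch, known_type = type,
                                           row.names = cell_ids))
    list(matrix = mat,
         truth = list(cell_type = type, pseudotime = pseudotime,
                      batch = batch, marker_of = marker_of),
         spec = spec)
  })
}

#' Probability of capturing a rare cell type
#'
#' Analytic planner for the number of cells to sequence: the probability of
#' drawing at least `m_min` cells of a type present at frequency `p` among
#' `n` sampled cells, `P(X >= m_min)` for `X ~ Binomial(n, p)`, computed
#' with the numerically stable binomial tail.
#'
#' @param n number of cells sampled (>= 0).
#' @param p population frequency of the type, in (0, 1).
#' @param m_min minimum number of cells required (>= 0).
#' @return a probability (vectorised over `n`).
#' @examples
#' expected_rare_detection(20000, 0.003, 10)
#' @export
expected_rare_detection <- function(n, p, m_min) {
  if (any(p <= 0) || any(p >= 1)) stopf("p must lie strictly in (0, 1)")
  if (any(m_min < 0)) stopf("m_min must be >= 0")
  if (any(n < 0)) stopf("n must be >= 0")
  # m_min = 0 falls out naturally: P(X > -1) = 1
  stats::pbinom(m_min - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Marker reference from generator ground truth
#'
#' Convenience: turns the `marker_of` map returned by [generate_dataset()]
#' into the named list of marker genes per type used by [marker_score()].
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @return named list, type -> character vector of marker gene IDs.
#' @export
truth_markers <- function(truth) {
  mk <- truth$marker_of[!is.na(truth$marker_of)]
  split(names(mk), mk)
}
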