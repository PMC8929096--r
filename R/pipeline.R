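# Orchestration of the full ladder experiment: simulate or load a pool,
# preprocess, run the per-size analyses, assemble saturation curves and a
# recommendation, and write a report bundle.

#' Configuration for a ladder experiment
#'
#' Collects every tunable of [run_experiment()] with the package defaults.
#' All defaults are overridable; unknown names are an error.
#'
#' @param input a `synthetic_spec` (the pool is simulated, ground truth
#'   retained), an [sc_expression], or a path understood by
#'   [read_counts()].
#' @param ladder_sizes ladder of cell numbers; default
#'   [default_ladder_sizes()] of the filtered pool.
#' @param ladder_mode `"independent"` or `"nested"`.
#' @param seed master seed (default 1234) expanded per stage and size.
#' @param min_cells_per_gene,min_genes_per_cell filter thresholds.
#' @param scale_factor log-normalisation pseudo-depth.
#' @param n_hvg highly variable genes per (sub)sample.
#' @param n_pcs PCs used downstream (default 30).
#' @param k_neighbors,prune SNN graph parameters.
#' @param resolution Louvain resolution (default 1.0).
#' @param markers named list type -> marker genes; defaults to the
#'   generator's ground-truth markers when simulating.
#' @param deg_min_pct,deg_logfc,deg_q one-vs-rest DEG parameters.
#' @param run_jackstraw,run_annotation,run_deg,run_trajectory stage
#'   toggles. JackStraw is off by default (it is the most expensive stage
#'   at large sizes).
#' @param jackstraw_n_pcs,jackstraw_reps,jackstraw_fraction JackStraw
#'   parameters.
#' @param trajectory_types length-2 type vector for the pseudotime stage;
#'   defaults to the simulated trajectory's source/sink when available.
#' @param agreement_replicates ladder draws used for the agreement-vs-
#'   reference curve (default 1). With more than one, additional seeded
#'   ladders are clustered and the curve aggregates replicates by median
#'   with IQR dispersion; sampling noise at small sizes otherwise
#'   dominates the ordering of neighbouring ladder steps.
#' @param agreement_replicate_sizes sizes the extra ladders cover
#'   (default `NULL` = all proper subsample sizes). Restricting them to
#'   the small sizes, where draw-to-draw dispersion actually dominates,
#'   keeps replicate cost proportionate.
#' @param epsilon plateau tolerance.
#' @param out_dir optional directory for the report bundle.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(input,
                       ladder_sizes = NULL,
                       ladder_mode = "independent",
                       seed = 1234,
                       min_cells_per_gene = 3,
                       min_genes_per_cell = 200,
                       scale_factor = 10000,
                       n_hvg = 2000,
                       n_pcs = 30,
                       k_neighbors = 20,
                       prune = 1 / 15,
                       resolution = 1.0,
                       markers = NULL,
                       deg_min_pct = 0.25,
                       deg_logfc = 0.25,
                       deg_q = 0.05,
                       run_jackstraw = FALSE,
                       run_annotation = TRUE,
                       run_deg = TRUE,
                       run_trajectory = FALSE,
                       jackstraw_n_pcs = 20,
                       jackstraw_reps = 30,
                       jackstraw_fraction = 0.01,
                       trajectory_types = NULL,
                       agreement_replicates = 1,
                       agreement_replicate_sizes = NULL,
                       epsilon = 0.05,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.character(cfg$input) && !file.exists(cfg$input) &&
      !dir.exists(cfg$input))
    stopf("input path does not exist: %s", cfg$input)
  if (!is.null(cfg$ladder_sizes) && any(diff(cfg$ladder_sizes) <= 0))
    stopf("ladder_sizes must be strictly increasing")
  structure(cfg, class = "run_config")
}

per_size_analysis <- function(nm_sub, ref_assignment, cfg, size_index,
                              truth = NULL) {
  res <- list()
  nm_sub <- select_hvg(nm_sub, min(cfg$n_hvg, nrow(nm_sub$values)))
  batch <- if (!is.null(nm_sub$meta) && "batch" %in% colnames(nm_sub$meta))
    nm_sub$meta$batch
  pca <- run_pca(nm_sub, n_pcs = min(cfg$n_pcs, ncol(nm_sub$values) - 1),
                 batch = batch)
  res$pca <- pca
  res$pca$loadings <- NULL      # scores suffice downstream; keep runs lean
  cl <- cluster_graph(
    build_snn(pca, k_neighbors = min(cfg$k_neighbors,
                                     nrow(pca$scores) - 1),
              prune = cfg$prune, dims = cfg$n_pcs),
    resolution = cfg$resolution,
    seed = derive_seed(cfg$seed, 1000 + size_index),
    n_pcs_used = pca$n_pcs)
  res$clusters <- cl
  if (!is.null(ref_assignment))
    res$agreement <- compare_to_reference(cl, ref_assignment)
  if (cfg$run_annotation && !is.null(cfg$markers)) {
    ann <- marker_score(nm_sub, cl, cfg$markers)
    res$annotation <- ann
    # per-cell type labels via the cluster assignment
    ct <- ann$assignment[as.character(cl$assignment)]
    names(ct) <- names(cl$assignment)
    res$cell_types <- ct
    if (cfg$run_deg) {
      keep <- ct != "unassigned"
      if (length(unique(ct[keep])) >= 2) {
        res$deg <- suppressWarnings(
          find_markers(nm_sub, ct[keep], only_pos = TRUE,
                       min_pct = cfg$deg_min_pct,
                       logfc_threshold = cfg$deg_logfc))
      }
    }
  }
  if (cfg$run_jackstraw) {
    js <- jackstraw(nm_sub, n_pcs = cfg$jackstraw_n_pcs,
                    n_reps = cfg$jackstraw_reps,
                    perm_fraction = cfg$jackstraw_fraction,
                    seed = derive_seed(cfg$seed, 2000 + size_index),
                    batch = batch)
    res$n_significant_pcs <- js$n_significant
  }
  if (cfg$run_trajectory && !is.null(cfg$trajectory_types)) {
    lab <- if (!is.null(truth)) truth$cell_type[rownames(pca$scores)]
           else res$cell_types
    res$trajectory <- tryCatch(
      fit_sample_trajectory(nm_sub, lab, cfg$trajectory_types,
                            n_hvg = cfg$n_hvg,
                            seed = derive_seed(cfg$seed, 3000 + size_index)),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "trajectory_failure"))
  }
  res
}

#' Run the full saturation experiment
#'
#' Simulates or loads a pool, filters and log-normalises it, draws the
#' subsampling ladder, analyses every size (HVG selection, PCA, SNN +
#' Louvain clustering, agreement with the full-pool reference clustering,
#' marker annotation, one-vs-rest DEGs, optionally JackStraw and the
#' pseudotime fit), assembles saturation curves and emits a recommended
#' cell number. Per-size stage failures (e.g. a trajectory at very small
#' sizes) are recorded without aborting the ladder. Reruns with the same
#' config are deterministic.
#'
#' @param cfg a [run_config()].
#' @return an object of class `sc_saturation_run`: the config, `truth`
#'   (when simulated), `ladder`, `reference` (full-pool clustering and
#'   annotation), `per_size` results, `agreement` (size x index table),
#'   `curves`, `recovery`, `recommendation`, and `errors`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  pool <- cfg$input
  if (inherits(pool, "synthetic_spec")) {
    sim <- generate_dataset(pool)
    pool <- sim$matrix
    truth <- sim$truth
    if (is.null(cfg$markers)) cfg$markers <- truth_markers(truth)
    if (is.null(cfg$trajectory_types) && !is.null(sim$spec$trajectory))
      cfg$trajectory_types <- c(sim$spec$trajectory$source,
                                sim$spec$trajectory$sink)
  } else if (is.character(pool)) {
    pool <- read_counts(pool)
  }
  stopifnot(inherits(pool, "sc_expression"))

  pool <- filter_matrix(pool, cfg$min_cells_per_gene, cfg$min_genes_per_cell)
  nm <- normalize_log(pool, cfg$scale_factor)
  sizes <- cfg$ladder_sizes %||% default_ladder_sizes(ncol(pool$counts))
  sizes <- sizes[sizes <= ncol(pool$counts)]
  ladder <- make_ladder(pool, sizes, mode = cfg$ladder_mode, seed = cfg$seed)

  # full-pool reference (also the last ladder entry when sizes end at pool)
  ref <- per_size_analysis(nm, NULL, cfg, size_index = 0, truth = truth)

  per_size <- list()
  errors <- list()
  pool_n <- ncol(pool$counts)
  for (k in seq_along(sizes)) {
    s <- as.character(sizes[k])
    if (sizes[k] == pool_n) {
      # the full-pool ladder entry IS the reference analysis; comparing
      # it with itself is trivial, so no agreement row is recorded
      per_size[[s]] <- ref
      next
    }
    nm_sub <- subset_norm(nm, ladder$draws[[s]])
    per_size[[s]] <- tryCatch(
      per_size_analysis(nm_sub, ref$clusters$assignment, cfg,
                        size_index = k, truth = truth),
      error = function(e) {
        errors[[s]] <<- conditionMessage(e)
        NULL
      })
    rm(nm_sub); gc(verbose = FALSE, full = TRUE)
  }
  ok <- !vapply(per_size, is.null, logical(1))
  per_size <- per_size[ok]

  agreement <- do.call(rbind, lapply(names(per_size), function(s) {
    ag <- per_size[[s]]$agreement
    if (is.null(ag)) return(NULL)
    data.frame(size = as.integer(s), replicate = 1L, RI = ag$RI, MA = ag$MA,
               HA = ag$HA, FM = ag$FM, JI = ag$JI)
  }))

  # extra seeded ladders, clustered only, to put replicate dispersion on
  # the agreement curve
  if (cfg$agreement_replicates > 1 && !is.null(agreement)) {
    cl_cfg <- cfg
    cl_cfg$run_annotation <- cl_cfg$run_deg <- FALSE
    cl_cfg$run_jackstraw <- cl_cfg$run_trajectory <- FALSE
    for (r in 2:cfg$agreement_replicates) {
      lad_r <- make_ladder(pool, sizes, mode = cfg$ladder_mode,
                           seed = derive_seed(cfg$seed, 7000 + r))
      rep_sizes <- cfg$agreement_replicate_sizes %||% sizes
      for (k in seq_along(sizes)) {
        if (sizes[k] == pool_n || !(sizes[k] %in% rep_sizes)) next
        s <- as.character(sizes[k])
        res_r <- tryCatch(
          per_size_analysis(subset_norm(nm, lad_r$draws[[s]]),
                            ref$clusters$assignment, cl_cfg,
                            size_index = 1000 * r + k),
          error = function(e) NULL)
        if (!is.null(res_r) && !is.null(res_r$agreement)) {
          ag <- res_r$agreement
          agreement <- rbind(agreement, data.frame(
            size = as.integer(s), replicate = r, RI = ag$RI, MA = ag$MA,
            HA = ag$HA, FM = ag$FM, JI = ag$JI))
        }
        gc(FALSE)
      }
    }
    agreement <- agreement[order(agreement$size, agreement$replicate), ]
    rownames(agreement) <- NULL
  }

  curves <- list()
  if (!is.null(agreement) && length(unique(agreement$size)) >= 3)
    curves$agreement_HA <- build_curve(
      split(agreement$HA, agreement$size),
      metric = "agreement_HA", epsilon = cfg$epsilon)

  discovered <- NULL
  if (cfg$run_annotation && !is.null(cfg$markers)) {
    ann_sets <- lapply(per_size, function(r) r$annotation$assignment)
    ann_sets <- ann_sets[!vapply(ann_sets, is.null, logical(1))]
    if (length(ann_sets) >= 3) {
      discovered <- types_discovered(ann_sets)
      curves$discovered_types <- build_curve(
        stats::setNames(as.list(discovered$counts$n_types),
                        discovered$counts$size),
        metric = "discovered_types", epsilon = cfg$epsilon)
    }
  }

  recovery <- NULL
  if (cfg$run_deg) {
    degs <- lapply(per_size, function(r) r$deg)
    degs <- degs[!vapply(degs, is.null, logical(1))]
    if (length(degs) >= 2) {
      recovery <- tryCatch(recovery_analysis(degs, q_cutoff = cfg$deg_q),
                           error = function(e) NULL)
      # the saturation curve tracks recovery of the full-pool DEG set
      # over proper subsamples: the pool recovering its own set (and the
      # union's small-sample-only members) carries no size information
      if (!is.null(recovery)) {
        rsub <- recovery$summary[recovery$summary$size < pool_n, ]
        if (nrow(rsub) >= 3)
          curves$deg_recovery <- build_curve(
            stats::setNames(as.list(rsub$recovered_largest), rsub$size),
            metric = "deg_recovery", epsilon = cfg$epsilon)
      }
    }
  }

  if (cfg$run_jackstraw) {
    nsig <- lapply(per_size, function(r) r$n_significant_pcs)
    nsig <- nsig[!vapply(nsig, is.null, logical(1))]
    if (length(nsig) >= 3)
      curves$significant_pcs <- build_curve(nsig, metric = "significant_pcs",
                                            epsilon = cfg$epsilon)
  }

  recommendation <- if (length(curves)) recommend(curves) else NULL

  run <- structure(
    list(config = cfg, truth = truth, pool_size = ncol(pool$counts),
         ladder = ladder, reference = ref, per_size = per_size,
         agreement = agreement, discovered = discovered,
         curves = curves, recovery = recovery,
         recommendation = recommendation, errors = errors),
    class = "sc_saturation_run")
  if (!is.null(cfg$out_dir)) write_report(run, cfg$out_dir)
  run
}

#' @export
print.sc_saturation_run <- function(x, ...) {
  cat(sprintf("<sc_saturation_run> pool of %d cells, ladder %s\n",
              x$pool_size, paste(x$ladder$sizes, collapse = "/")))
  if (!is.null(x$agreement)) {
    cat("agreement with full-pool clustering:\n")
    print(x$agreement, row.names = FALSE)
  }
  if (!is.null(x$recommendation)) print(x$recommendation)
  if (length(x$errors))
    cat(sprintf("stage failures at sizes: %s\n",
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}

#' Write the report bundle of a run
#'
#' Per-stage TSV/CSV artifacts plus a machine-readable `summary.json` and
#' a `run_log.txt` echoing package version, seed and every effective
#' parameter.
#'
#' @param run an `sc_saturation_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ladder(run$ladder, file.path(dir, "ladder.tsv"))
  if (!is.null(run$truth)) write_truth(run$truth, file.path(dir, "truth.tsv"))
  if (!is.null(run$agreement))
    utils::write.csv(run$agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
  for (s in names(run$per_size)) {
    r <- run$per_size[[s]]
    data.table::fwrite(
      data.table::data.table(cell_id = names(r$clusters$assignment),
                             cluster = unname(r$clusters$assignment)),
      file.path(dir, sprintf("clusters_%s.tsv", s)), sep = "\t")
    if (!is.null(r$deg))
      data.table::fwrite(r$deg, file.path(dir, sprintf("deg_%s.tsv", s)),
                         sep = "\t")
  }
  if (length(run$curves)) {
    cdat <- do.call(rbind, lapply(run$curves, function(cu)
      cbind(metric = cu$metric, cu$data)))
    utils::write.csv(cdat, file.path(dir, "curves.csv"), row.names = FALSE)
  }
  summary <- list(
    pool_size = run$pool_size,
    ladder_sizes = run$ladder$sizes,
    seed = run$config$seed,
    n_clusters = lapply(run$per_size, function(r) r$clusters$n_clusters),
    agreement = run$agreement,
    discovered_types = if (!is.null(run$discovered)) run$discovered$counts,
    deg_recovery = if (!is.null(run$recovery)) run$recovery$summary,
    recommendation = if (!is.null(run$recommendation))
      list(size = run$recommendation$size,
           action = run$recommendation$action,
           per_metric = as.list(run$recommendation$per_metric)),
    errors = run$errors)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(c(
    sprintf("scSaturation %s", as.character(utils::packageVersion("scSaturation"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "effective parameters:",
    vapply(names(run$config), function(nm) {
      v <- run$config[[nm]]
      sprintf("  %s = %s", nm,
              if (is.null(v)) "NULL"
              else if (is.atomic(v)) paste(utils::head(v, 20), collapse = ", ")
              else class(v)[1])
    }, character(1))),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}
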