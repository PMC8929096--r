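# Cluster-to-type assignment by markers, bulk correlation, ICI scores.

test_that("marker_score assigns every cluster its true type on clean data", {
  mc <- multi_type_clustered()
  markers <- truth_markers(mc$sim$truth)
  ann <- marker_score(mc$nm, mc$clusters, markers)
  truth <- mc$sim$truth$cell_type[names(mc$clusters$assignment)]
  # majority true type per cluster
  maj <- vapply(rownames(ann$scores), function(cl)
    names(sort(table(truth[mc$clusters$assignment == as.integer(cl)]),
               decreasing = TRUE))[1], character(1))
  expect_equal(unname(ann$assignment), unname(maj))
  expect_false(any(ann$assignment == "unassigned"))
})

test_that("marker_score handles degenerate references", {
  nm <- two_type_norm()
  cl <- setNames(rep(0:1, length.out = ncol(nm$values)), colnames(nm$values))
  expect_error(marker_score(nm, cl, list(t = c("nope1", "nope2"))),
               "no marker genes")
  # uniform expression: a gene set with no contrast scores ~0 -> unassigned
  flat <- list(t = rownames(nm$values)[1:50])
  sim <- two_type_sim()
  nonmk <- names(sim$truth$marker_of)[is.na(sim$truth$marker_of)]
  flat$t <- intersect(nonmk, rownames(nm$values))[1:50]
  ann <- marker_score(nm, cl, flat)
  expect_true(all(abs(ann$scores) < 0.05))
})

test_that("over-resolved clusters map non-injectively onto one type", {
  sim <- two_type_sim()
  nm <- two_type_norm()
  truth <- sim$truth$cell_type[colnames(nm$values)]
  # split type alpha artificially into two clusters
  lab <- ifelse(truth == "alpha", 0L, 2L)
  alpha_cells <- which(truth == "alpha")
  lab[alpha_cells[seq_len(length(alpha_cells) %/% 2)]] <- 1L
  names(lab) <- colnames(nm$values)
  ann <- marker_score(nm, lab, truth_markers(sim$truth))
  expect_equal(unname(ann$assignment[c("0", "1")]), c("alpha", "alpha"))
  expect_equal(unname(ann$assignment["2"]), "beta")
})

test_that("bulk_spearman is exact against itself and tracks permutations", {
  mc <- multi_type_clustered()
  cm <- scSaturation:::cluster_means(mc$nm$values, mc$clusters)
  bulk <- cm$means
  colnames(bulk) <- paste0("type_", colnames(bulk))
  rho <- bulk_spearman(mc$nm, mc$clusters, bulk)
  expect_equal(unname(diag(rho)), rep(1, nrow(rho)), tolerance = 1e-10)

  perm <- sample(ncol(bulk))
  rho2 <- bulk_spearman(mc$nm, mc$clusters, bulk[, perm])
  amax <- apply(rho2, 1, which.max)
  expect_equal(unname(colnames(bulk)[perm][amax]), colnames(bulk))

  expect_error(bulk_spearman(mc$nm, mc$clusters,
                             bulk[1:5, , drop = FALSE]), "shared")
})

test_that("bulk_spearman argmax survives heavy noise on the reference", {
  mc <- multi_type_clustered()
  cm <- scSaturation:::cluster_means(mc$nm$values, mc$clusters)
  set.seed(13)
  sds <- apply(cm$means, 1, sd)
  bulk <- cm$means + matrix(rnorm(length(cm$means), sd = sds),
                            nrow(cm$means))
  colnames(bulk) <- colnames(cm$means)
  rho <- bulk_spearman(mc$nm, mc$clusters, bulk)
  hits <- mean(colnames(rho)[apply(rho, 1, which.max)] == rownames(rho))
  expect_gte(hits, 0.9)
})

test_that("ICI scores behave per construction and sum to one", {
  sim <- two_type_sim()
  nm <- two_type_norm()
  mk <- truth_markers(sim$truth)
  spec_tab <- do.call(rbind, lapply(names(mk), function(ty)
    data.frame(gene = mk[[ty]], type = ty, weight = 1)))
  res <- ici_assign(nm, spec_tab, n_boot = 200, seed = 1)
  rs <- rowSums(res$ici)
  detected <- rs > 0
  expect_equal(unname(rs[detected]), rep(1, sum(detected)), tolerance = 1e-9)
  expect_true(all(res$padj >= res$p - 1e-12))
  # BH is rank-monotone
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-12 | diff(res$p[o]) > 0))
  # accuracy against ground truth
  truth <- sim$truth$cell_type[rownames(res$ici)]
  assigned <- res$assignment != "unassigned"
  expect_gte(mean(res$assignment[assigned] == truth[assigned]), 0.85)
  expect_gte(mean(assigned), 0.5)
})

test_that("symmetric ICI evidence stays unassigned", {
  nm <- two_type_norm()
  genes <- rownames(nm$values)[1:20]
  spec_tab <- rbind(data.frame(gene = genes, type = "A", weight = 1),
                    data.frame(gene = genes, type = "B", weight = 1))
  res <- ici_assign(nm, spec_tab, n_boot = 100, seed = 2)
  expect_true(all(res$assignment == "unassigned"))
  detected <- rowSums(res$ici) > 0
  expect_equal(unname(res$ici[detected, "A"]),
               rep(0.5, sum(detected)), tolerance = 1e-9)
})

test_that("types_discovered counts first appearances across sizes", {
  ann <- list("500" = c("0" = "hair", "1" = "cortex"),
              "1000" = c("0" = "hair", "1" = "cortex", "2" = "unassigned"),
              "3000" = c("0" = "hair", "1" = "cortex", "2" = "stele"))
  td <- types_discovered(ann)
  expect_equal(td$counts$n_types, c(2, 2, 3))
  expect_equal(td$first_discovery[["stele"]], 3000L)
  expect_equal(td$first_discovery[["hair"]], 500L)
  # nondecreasing under nesting by construction here
  expect_true(all(diff(td$counts$n_types) >= 0))
})
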