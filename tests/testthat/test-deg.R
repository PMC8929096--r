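# One-vs-rest DEG detection, ROC power, recovery analysis.

test_that("roc_power matches hand-worked midrank example and trivial cases", {
  # in {3,4,5} vs out {1,2,3}: 8 wins + 1 tie over 9 pairs -> 8.5/9? No:
  # pairs (3,1)(3,2) win, (3,3) tie, (4,*) 3 wins, (5,*) 3 wins = 8 + 0.5
  expect_equal(roc_power(x_in = c(3, 4, 5), x_out = c(1, 2, 3))$auc, 8.5 / 9)
  expect_equal(roc_power(x_in = c(10, 11), x_out = c(1, 2))$auc, 1)
  expect_equal(roc_power(x_in = c(10, 11), x_out = c(1, 2))$power, 1)
  expect_equal(roc_power(x_in = rep(2, 5), x_out = rep(2, 7))$auc, 0.5)
  expect_equal(roc_power(x_in = rep(2, 5), x_out = rep(2, 7))$power, 0)
})

test_that("AUC equals the all-pairs oracle on random instances", {
  set.seed(14)
  for (i in 1:60) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    x1 <- sample(0:5, n1, replace = TRUE) + rnorm(n1, 0, 0.01 * (i %% 2))
    x2 <- sample(0:5, n2, replace = TRUE)
    expect_equal(roc_power(x_in = x1, x_out = x2)$auc, brute_auc(x1, x2),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p-values agree with stats::wilcox.test", {
  set.seed(15)
  nm <- two_type_norm()
  sim <- two_type_sim()
  labels <- sim$truth$cell_type[colnames(nm$values)]
  tab <- find_markers(nm, labels, only_pos = FALSE, min_pct = 0.1,
                      logfc_threshold = 0.1)
  expect_gt(nrow(tab), 10)
  pick <- tab[sample(nrow(tab), 10), ]
  for (r in seq_len(nrow(pick))) {
    v <- as.numeric(nm$values[pick$gene[r], ])
    ing <- labels == pick$group[r]
    ref <- suppressWarnings(
      wilcox.test(v[ing], v[!ing], exact = FALSE, correct = TRUE))$p.value
    expect_equal(pick$p_value[r], ref, tolerance = 1e-10)
  }
})

test_that("find_markers applies the detection and fold-change prefilters", {
  # a gene detected in 10% of both groups is never tested at min.pct 0.25
  set.seed(16)
  n <- 400
  counts <- Matrix::Matrix(0, 4, n, sparse = TRUE,
    dimnames = list(c("rare_gene", "marker", "flat", "filler"),
                    sprintf("c%d", 1:n)))
  counts["rare_gene", sample(n, 40)] <- 1
  grp <- rep(c("g1", "g2"), each = n / 2)
  names(grp) <- colnames(counts)
  counts["marker", grp == "g1"] <- rpois(n / 2, 8)
  counts["marker", grp == "g2"] <- rpois(n / 2, 1)
  counts["flat", ] <- rpois(n, 5)
  # keep depths balanced so "flat" carries no composition artifact
  counts["filler", grp == "g2"] <- rpois(n / 2, 7)
  nm <- normalize_log(sc_expression(counts), 100)
  tab <- find_markers(nm, grp, only_pos = TRUE, min_pct = 0.25,
                      logfc_threshold = 0.25)
  expect_false("rare_gene" %in% tab$gene)
  expect_false("flat" %in% tab$gene)      # no fold change
  expect_true("marker" %in% tab$gene[tab$group == "g1"])
  expect_lt(tab$q_value[tab$gene == "marker" & tab$group == "g1"], 0.05)
})

test_that("find_markers output is invariant to cell order", {
  nm <- two_type_norm()
  sim <- two_type_sim()
  labels <- sim$truth$cell_type[colnames(nm$values)]
  t1 <- find_markers(nm, labels)
  set.seed(17)
  perm <- sample(colnames(nm$values))
  nm2 <- subset_norm(nm, perm)
  t2 <- find_markers(nm2, labels[perm])
  o1 <- t1[order(t1$gene, t1$group), ]
  o2 <- t2[order(t2$gene, t2$group), ]
  expect_equal(o1$p_value, o2$p_value, tolerance = 1e-12)
  expect_equal(o1$auc, o2$auc, tolerance = 1e-12)
})

test_that("planted markers are detected with high power", {
  spec <- synthetic_spec(n_cells = 2000, n_genes = 500,
                         type_names = c("a", "b"), proportions = c(0.5, 0.5),
                         markers_per_type = 15, marker_logfc = log(4),
                         seed = 23)
  hits <- 0; total <- 0
  for (s in 1:2) {
    spec$seed <- 23 + s
    sim <- generate_dataset(spec)
    nm <- normalize_log(filter_matrix(sim$matrix, 3, 20))
    labels <- sim$truth$cell_type[colnames(nm$values)]
    tab <- find_markers(nm, labels)
    mk <- sim$truth$marker_of[!is.na(sim$truth$marker_of)]
    mk <- mk[names(mk) %in% rownames(nm$values)]
    found <- paste(tab$gene[tab$q_value < 0.05], tab$group[tab$q_value < 0.05])
    hits <- hits + sum(paste(names(mk), mk) %in% found)
    total <- total + length(mk)
  }
  expect_gte(hits / total, 0.95)
})

test_that("label permutation yields a calibrated null", {
  nm <- two_type_norm()
  sim <- two_type_sim()
  labels <- sim$truth$cell_type[colnames(nm$values)]
  set.seed(18)
  fp <- replicate(20, {
    perm <- setNames(sample(labels), names(labels))
    tab <- find_markers(nm, perm, only_pos = FALSE, min_pct = 0.1,
                        logfc_threshold = 0)
    if (nrow(tab)) sum(tab$q_value < 0.05) / nrow(tab) else 0
  })
  expect_lte(mean(fp), 0.05)
})

test_that("groups with fewer than 3 cells are skipped with a record", {
  nm <- two_type_norm()
  labels <- setNames(rep("big", ncol(nm$values)), colnames(nm$values))
  labels[1:2] <- "tiny"
  labels[3:50] <- "mid"
  expect_warning(tab <- find_markers(nm, labels), "tiny")
  expect_equal(attr(tab, "skipped"), "tiny")
  expect_false("tiny" %in% tab$group)
})

test_that("recovery_analysis computes union, fractions and AUC split", {
  mk_tab <- function(genes, group, auc, q = 0.01)
    data.frame(gene = genes, group = group, log_fc = 1, pct_in = 1,
               pct_out = 0, p_value = q, q_value = q, auc = auc,
               power = 2 * abs(auc - 0.5))
  degs <- list(
    "500" = mk_tab(c("g1", "g2"), "t", c(0.9, 0.95)),
    "1000" = mk_tab(c("g1", "g2", "g3"), "t", c(0.9, 0.94, 0.7)),
    "2000" = mk_tab(c("g1", "g2", "g3", "g4"), "t", c(0.9, 0.93, 0.71, 0.6)))
  rep <- recovery_analysis(degs)
  expect_equal(length(rep$union_keys), 4)
  expect_equal(rep$summary$recovered_union, c(2 / 4, 3 / 4, 1))
  expect_equal(rep$summary$recovered_largest, c(2 / 4, 3 / 4, 1))
  expect_equal(rep$summary$n_unique, c(0, 0, 1))
  expect_setequal(rep$common_keys, c("g1|t", "g2|t"))
  expect_setequal(rep$unique_keys, "g4|t")
  expect_gt(median(rep$auc_common), median(rep$auc_unique))

  single <- recovery_analysis(degs["2000"])
  expect_equal(single$summary$recovered_union, 1)
})
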