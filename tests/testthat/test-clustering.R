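# Pair counting, the five agreement indices, SNN graph and Louvain.

test_that("pair_counts matches hand enumeration and the brute-force oracle", {
  expect_equal(unclass(pair_counts(c(1, 1, 2, 2), c(1, 1, 2, 2)))[1:4],
               list(a = 2, b = 0, c = 0, d = 4))
  expect_equal(unclass(pair_counts(c(1, 1, 1, 1), c(1, 2, 3, 4)))[1:4],
               list(a = 0, b = 6, c = 0, d = 0))
  expect_equal(unclass(pair_counts(c(1, 1, 1, 2, 2, 2),
                                   c(1, 1, 2, 2, 3, 3)))[1:4],
               list(a = 2, b = 4, c = 1, d = 8))
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    pc <- pair_counts(a, b)
    oracle <- brute_pair_counts(a, b)
    expect_equal(c(pc$a, pc$b, pc$c, pc$d), unname(oracle))
    expect_equal(pc$a + pc$b + pc$c + pc$d, n * (n - 1) / 2)
  }
})

test_that("pair_counts aligns named vectors and reports set mismatches", {
  a <- setNames(c(1, 1, 2), c("x", "y", "z"))
  b <- setNames(c(2, 1, 1), c("z", "x", "y"))   # same cells, other order
  pc <- pair_counts(a, b)
  expect_equal(pc$a, 3 - 2)  # pairs (x,y) together in both
  expect_error(pair_counts(a, setNames(1:3, c("x", "y", "w"))), "only in")
})

test_that("agreement indices match a hand-worked example and their limits", {
  pc <- pair_counts(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 3, 3))
  sc <- agreement_indices(pc)
  expect_equal(sc$RI, 10 / 15, tolerance = 1e-12)
  expect_equal(sc$HA, 24 / 99, tolerance = 1e-12)
  expect_equal(sc$FM, 2 / sqrt(18), tolerance = 1e-12)
  expect_equal(sc$JI, 2 / 7, tolerance = 1e-12)

  ident <- compare_partitions(c(1, 1, 2, 2, 3), c(5, 5, 7, 7, 9))
  expect_equal(ident$RI, 1); expect_equal(ident$HA, 1)
  expect_equal(ident$MA, 1); expect_equal(ident$FM, 1)
  expect_equal(ident$JI, 1)

  # one cluster vs all singletons: RI = 0
  degen <- compare_partitions(rep(1, 50), 1:50)
  expect_equal(degen$RI, 0)
  expect_equal(degen$FM, 0)
  expect_equal(degen$JI, 0)
})

test_that("all five indices equal the brute-force oracle on random pairs", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    ka <- sample(1:5, 1); kb <- sample(1:5, 1)
    a <- sample(seq_len(ka), n, replace = TRUE)
    b <- sample(seq_len(kb), n, replace = TRUE)
    got <- compare_partitions(a, b)
    want <- brute_indices(a, b)
    for (idx in c("RI", "MA", "HA", "FM", "JI"))
      expect_equal(got[[idx]], want[[idx]], tolerance = 1e-12,
                   label = sprintf("%s on case %d", idx, i))
  }
})

test_that("indices are invariant to relabeling and suitably symmetric", {
  set.seed(5)
  a <- sample(1:4, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  perm <- c(3, 1, 4, 2)
  got1 <- compare_partitions(a, b)
  got2 <- compare_partitions(perm[a], b)
  expect_equal(got1, got2)
  fwd <- compare_partitions(a, b); rev <- compare_partitions(b, a)
  for (idx in c("RI", "HA", "MA"))
    expect_equal(fwd[[idx]], rev[[idx]], tolerance = 1e-12)
})

test_that("chance-corrected indices centre on zero under relabeling", {
  set.seed(8)
  a <- sample(1:5, 200, replace = TRUE)
  b <- sample(1:4, 200, replace = TRUE)
  ha <- ma <- numeric(100)
  for (i in 1:100) {
    sc <- compare_partitions(a, sample(b))
    ha[i] <- sc$HA; ma[i] <- sc$MA
  }
  expect_lt(abs(mean(ha)), 0.02)
  expect_lt(abs(mean(ma)), 0.02)
})

test_that("two disconnected cliques form exactly two clusters", {
  g <- igraph::make_full_graph(8) + igraph::make_full_graph(8)
  igraph::V(g)$name <- sprintf("v%d", 1:16)
  igraph::E(g)$weight <- 1
  cl <- cluster_graph(g, resolution = 1, seed = 1)
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(cl$assignment[1:8])), 1)
  expect_equal(length(unique(cl$assignment[9:16])), 1)
  expect_setequal(unique(cl$assignment), c(0, 1))
})

test_that("SNN graph respects geometry: separated blobs never connect", {
  set.seed(3)
  X <- rbind(matrix(rnorm(100 * 5), 100, 5),
             matrix(rnorm(100 * 5, mean = 50), 100, 5))
  rownames(X) <- sprintf("c%d", 1:200)
  g <- build_snn(X, k_neighbors = 20, dims = 5)
  el <- igraph::as_edgelist(g)
  side <- function(v) as.integer(sub("c", "", v)) <= 100
  expect_true(all(side(el[, 1]) == side(el[, 2])))
})

test_that("duplicate points are strongly connected; k = n-1 gives a complete graph", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3)
  X[2, ] <- X[1, ]                       # exact duplicate
  rownames(X) <- sprintf("c%d", 1:30)
  k <- 10
  g <- build_snn(X, k_neighbors = k, dims = 3, prune = 0)
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("c1", "c2"))]
  expect_gte(w, (k - 1) / (k + 1))

  g2 <- build_snn(X, k_neighbors = 29, dims = 3)
  expect_equal(igraph::ecount(g2), choose(30, 2))
})

test_that("clusters recover planted types and resolution increases cluster count", {
  mc <- multi_type_clustered()
  truth <- mc$sim$truth$cell_type[names(mc$clusters$assignment)]
  sc <- compare_partitions(mc$clusters$assignment, truth)
  expect_gte(sc$HA, 0.8)

  n_at <- vapply(c(0.2, 1.0, 2.0), function(r)
    cluster_graph(build_snn(mc$pca, 20), resolution = r, seed = 1)$n_clusters,
    numeric(1))
  expect_true(n_at[1] <= n_at[2] && n_at[2] <= n_at[3])
})

test_that("compare_to_reference restricts the reference to the subsample", {
  mc <- multi_type_clustered()
  cl <- mc$clusters
  sub_cells <- names(cl$assignment)[1:500]
  sub <- cl$assignment[sub_cells]
  direct <- compare_partitions(sub, cl$assignment[sub_cells])
  via <- compare_to_reference(sub, cl$assignment)
  expect_equal(via, direct)
  expect_equal(via$RI, 1)
  expect_error(compare_to_reference(setNames(1, "nope"), cl$assignment),
               "missing|no subsample")
})
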