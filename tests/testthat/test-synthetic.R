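# Generator ground truth: determinism, marker effect sizes, rare-type
# sampling, and the binomial capture planner.

test_that("identical specs give bit-identical datasets", {
  spec <- synthetic_spec(n_cells = 300, n_genes = 200, seed = 9)
  s1 <- generate_dataset(spec)
  s2 <- generate_dataset(spec)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  expect_identical(s1$truth, s2$truth)
})

test_that("spec validation rejects bad inputs", {
  expect_error(synthetic_spec(proportions = c(0.5, 0.6),
                              type_names = c("a", "b")), "sum to 1")
  expect_error(synthetic_spec(n_genes = 10, markers_per_type = 5,
                              type_names = c("a", "b", "c"),
                              proportions = c(0.4, 0.3, 0.3)),
               "exceeds n_genes")
  expect_warning(generate_dataset(
    synthetic_spec(n_cells = 100, type_names = c("a", "b"),
                   proportions = c(0.999, 0.001), n_genes = 100,
                   markers_per_type = 5, seed = 1)),
    "expected count")
})

test_that("degenerate one-type, zero-noise spec gives homogeneous Poisson-like counts", {
  spec <- synthetic_spec(n_cells = 2000, n_genes = 150, type_names = "only",
                         proportions = 1, markers_per_type = 0,
                         marker_logfc = 0, dispersion = 0,
                         libsize_logparams = c(0, 0), seed = 3)
  sim <- generate_dataset(spec)
  x <- sim$matrix$counts
  mu <- Matrix::rowMeans(x)
  v <- Matrix::rowSums((x - mu)^2) / (ncol(x) - 1)
  keep <- mu > 0.05
  # Poisson: variance equals mean
  expect_lt(abs(median(v[keep] / mu[keep]) - 1), 0.1)
  # identical means across cells: two random halves agree within 4 SE
  half <- seq_len(1000)
  m1 <- Matrix::rowMeans(x[, half]); m2 <- Matrix::rowMeans(x[, -half])
  se <- sqrt(mu / 1000 * 2)
  expect_gt(mean(abs(m1 - m2)[keep] <= 4 * se[keep]), 0.95)
})

test_that("marker fold change is realised at the requested ratio", {
  spec <- synthetic_spec(n_cells = 2000, n_genes = 400,
                         type_names = c("a", "b"), proportions = c(0.5, 0.5),
                         markers_per_type = 10, marker_logfc = log(4),
                         libsize_logparams = c(0, 0), seed = 8)
  sim <- generate_dataset(spec)
  x <- sim$matrix$counts
  ty <- sim$truth$cell_type
  mk_a <- names(sim$truth$marker_of)[!is.na(sim$truth$marker_of) &
                                     sim$truth$marker_of == "a"]
  ok <- 0
  for (g in mk_a) {
    xa <- x[g, ty == "a"]; xb <- x[g, ty == "b"]
    r <- mean(xa) / mean(xb)
    se <- r * sqrt(var(xa) / (length(xa) * mean(xa)^2) +
                   var(xb) / (length(xb) * mean(xb)^2))
    ok <- ok + (abs(r - 4) <= 3 * se)
  }
  expect_gte(ok, 8)  # 3-SE band, 10 markers
  # pooled estimate tight around 4
  ratios <- vapply(mk_a, function(g)
    mean(x[g, ty == "a"]) / mean(x[g, ty == "b"]), numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.5)
})

test_that("rare-type counts follow the binomial sampling law", {
  spec <- synthetic_spec(n_cells = 10000, n_genes = 50,
                         type_names = c("common", "rare"),
                         proportions = c(0.997, 0.003),
                         markers_per_type = 5, seed = 12)
  sim <- suppressWarnings(generate_dataset(spec))
  n_rare <- sum(sim$truth$cell_type == "rare")
  lo <- qbinom(5e-4, 10000, 0.003)
  hi <- qbinom(1 - 5e-4, 10000, 0.003)
  expect_gte(n_rare, lo)
  expect_lte(n_rare, hi)
})

test_that("non-marker genes are independent of the type label", {
  spec <- synthetic_spec(n_cells = 5000, n_genes = 120,
                         type_names = c("a", "b"), proportions = c(0.5, 0.5),
                         markers_per_type = 10, marker_logfc = log(4),
                         libsize_logparams = c(0, 0), seed = 31)
  sim <- generate_dataset(spec)
  x <- sim$matrix$counts
  ty <- sim$truth$cell_type
  nonmk <- names(sim$truth$marker_of)[is.na(sim$truth$marker_of)][1:100]
  na <- sum(ty == "a"); nb <- sum(ty == "b")
  z <- vapply(nonmk, function(g) {
    xa <- x[g, ty == "a"]; xb <- x[g, ty == "b"]
    (mean(xa) - mean(xb)) / sqrt(var(xa) / na + var(xb) / nb)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(z, "pnorm")$p.value), 0.001)
})

test_that("trajectory cells carry pseudotime and interpolated profiles", {
  spec <- synthetic_spec(n_cells = 1500, n_genes = 300,
                         type_names = c("src", "snk", "other"),
                         proportions = c(0.3, 0.3, 0.4),
                         markers_per_type = 15, marker_logfc = log(6),
                         trajectory = list(source = "src", sink = "snk"),
                         seed = 4)
  sim <- generate_dataset(spec)
  pt <- sim$truth$pseudotime
  ty <- sim$truth$cell_type
  expect_true(all(is.na(pt[ty == "other"])))
  expect_true(all(!is.na(pt[ty %in% c("src", "snk")])))
  expect_true(all(pt[ty == "src"] < pt[ty == "snk"][1] |
                  is.na(pt[ty == "src"])) ||
              max(pt[ty == "src"]) <= min(pt[ty == "snk"]))
  # sink markers rise with pseudotime among trajectory cells
  mk_snk <- names(sim$truth$marker_of)[!is.na(sim$truth$marker_of) &
                                       sim$truth$marker_of == "snk"]
  traj <- names(pt)[!is.na(pt)]
  expr <- Matrix::colSums(sim$matrix$counts[mk_snk, traj])
  expect_gt(cor(expr, pt[traj], method = "spearman"), 0.5)
})

test_that("expected_rare_detection matches exact binomial summation", {
  expect_equal(expected_rare_detection(500, 0.01, 0), 1.0)
  expect_equal(expected_rare_detection(0, 0.01, 1), 0.0)
  oracle <- sum(dbinom(51:100, 100, 0.5))
  expect_equal(expected_rare_detection(100, 0.5, 51), oracle,
               tolerance = 1e-12)
  expect_error(expected_rare_detection(100, 1.2, 1), "p must")
  # vectorised over n and monotone
  p <- expected_rare_detection(c(100, 1000, 10000), 0.003, 5)
  expect_length(p, 3)
  expect_true(all(diff(p) > 0))
  expect_equal(p[3], sum(dbinom(5:10000, 10000, 0.003)), tolerance = 1e-12)
})
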