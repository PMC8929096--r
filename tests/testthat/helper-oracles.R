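# Independent brute-force oracles used to validate the fast
# implementations, plus small cached fixtures.

# O(n^2) pair enumeration: counts co-membership over every unordered pair.
brute_pair_counts <- function(a, b) {
  n <- length(a)
  cnt <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    k <- if (sa && sb) "a" else if (sa) "b" else if (sb) "c" else "d"
    cnt[k] <- cnt[k] + 1
  }
  cnt
}

# agreement indices straight from brute-force pair counts (formula-level
# re-derivation, no shared code with the package implementation)
brute_indices <- function(a_lab, b_lab) {
  pc <- brute_pair_counts(a_lab, b_lab)
  n <- length(a_lab)
  tot <- n * (n - 1) / 2
  a <- pc[["a"]]; b <- pc[["b"]]; cc <- pc[["c"]]; d <- pc[["d"]]
  Q <- (a + b) * (a + cc) + (cc + d) * (b + d)
  S <- 2 * a + n; Sr <- 2 * (a + b) + n; Sc <- 2 * (a + cc) + n
  E <- Sr * Sc / n^2
  list(RI = (a + d) / tot,
       HA = if (tot^2 - Q == 0) 1 else (tot * (a + d) - Q) / (tot^2 - Q),
       MA = if (abs((Sr + Sc) / 2 - E) < 1e-12) 1 else
         (S - E) / ((Sr + Sc) / 2 - E),
       FM = if ((a + b) == 0 || (a + cc) == 0) 0 else
         a / sqrt((a + b) * (a + cc)),
       JI = if ((a + b + cc) == 0) 1 else a / (a + b + cc))
}

# all-pairs AUC oracle: wins + half-ties over n_in * n_out comparisons
brute_auc <- function(x_in, x_out) {
  wins <- 0
  for (xi in x_in) for (xo in x_out)
    wins <- wins + (xi > xo) + 0.5 * (xi == xo)
  wins / (length(x_in) * length(x_out))
}

# Small structured dataset reused by several test files (two balanced
# types, clear markers), built once per test run.
fixture_env <- new.env(parent = emptyenv())

two_type_sim <- function() {
  if (is.null(fixture_env$two_type)) {
    spec <- synthetic_spec(
      n_cells = 1200, n_genes = 600, type_names = c("alpha", "beta"),
      proportions = c(0.5, 0.5), markers_per_type = 20,
      marker_logfc = log(4), seed = 42)
    fixture_env$two_type <- generate_dataset(spec)
  }
  fixture_env$two_type
}

two_type_norm <- function() {
  if (is.null(fixture_env$two_type_nm)) {
    sim <- two_type_sim()
    fixture_env$two_type_nm <-
      select_hvg(normalize_log(filter_matrix(sim$matrix, 3, 20)), 400)
  }
  fixture_env$two_type_nm
}

multi_type_sim <- function() {
  if (is.null(fixture_env$multi)) {
    spec <- synthetic_spec(
      n_cells = 3000, n_genes = 1200,
      type_names = paste0("t", 1:6),
      proportions = c(0.28, 0.22, 0.18, 0.14, 0.10, 0.08),
      markers_per_type = 30, marker_logfc = log(8), seed = 77)
    fixture_env$multi <- generate_dataset(spec)
  }
  fixture_env$multi
}

multi_type_clustered <- function() {
  if (is.null(fixture_env$multi_cl)) {
    sim <- multi_type_sim()
    nm <- select_hvg(normalize_log(filter_matrix(sim$matrix, 3, 20)), 800)
    pca <- run_pca(nm, 20)
    cl <- cluster_graph(build_snn(pca, 20), resolution = 1, seed = 1)
    fixture_env$multi_cl <- list(sim = sim, nm = nm, pca = pca, clusters = cl)
  }
  fixture_env$multi_cl
}
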