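---
title: "How many cells? Methods behind scSaturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many cells? Methods behind scSaturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Single-cell RNA-seq experiments buy information with cells: more cells
resolve more principal components, more clusters, rarer cell types, more
marker genes, and smoother differentiation trajectories — at a cost that
grows linearly. scSaturation asks the saturation question directly: given a
large pool of cells (real or simulated), how do the standard analysis
outputs change as ever larger subsamples are drawn, and at what size does
each output stop improving?

The package runs a *subsampling ladder* — by default 500, 1000, 3000, 5000,
10000, 20000, 30000 and 40000 cells plus the full pool, each drawn uniformly
without replacement from one integrated pool — and tracks five families of
outputs per size:

1. **Significant PCs** — a JackStraw permutation test per subsample.
2. **Clustering reliability** — SNN-graph Louvain clustering compared with
   the full-pool clustering through five pair-counting agreement indices.
3. **Cell-type discovery** — marker-based (and optionally bulk-correlation
   or ICI-based) annotation of clusters, counting types found per size.
4. **DEG recovery** — one-vs-rest Wilcoxon markers with ROC classification
   power, measured against the nonredundant union over all sizes.
5. **Pseudotime stability** — an MST pseudotime over a source/derivative
   type pair.

Each metric-versus-size curve is reduced to a plateau size, and the
recommendation is the largest plateau over the selected metrics.

# The synthetic pool

Every stage is testable without any download because the package ships a
generator with analytic ground truth. Counts follow a negative binomial
with mean `s_c * m_g * f_{g,t(c)} * b_{g,batch(c)}`:

* `m_g` — log-normal base means (`meanlog -1.8`, `sdlog 1.2`), giving
  roughly 1000 counts per cell over 3000 genes, typical of droplet data
  from plant tissue;
* `s_c` — log-normal depth factors (`sdlog 0.35`);
* `f` — multiplicative marker fold-change: each type owns a set of marker
  genes (planted in genes of at least median base mean, because curated
  identity markers are well-expressed genes); non-markers are independent
  of the type label. Marker sets are dealt to types in snake order of base
  mean so each type's markers carry near-equal total base mass: types then
  differ in *composition*, not expected total RNA. Without this balance,
  depth normalisation converts random differences in marker mass into a
  coordinated sub-threshold fold-change on every null gene, which noisy
  small-sample fold-change estimates push over the DEG prefilter — an
  artifact of the simulator, not a property being studied. A genuine
  composition shift remains along the differentiation continuum, where
  interpolated marker load varies with pseudotime;
* `b` — optional per-gene, per-batch log-normal shifts;
* dispersion 0.3 (`Var = mu + 0.3 mu^2`), the usual droplet-data order of
  magnitude. Dropout is implicit in NB sampling at low means; no extra
  zero-inflation layer is added, which keeps every expectation analytic.

`root_pool_spec()` is the preset used by the package's own end-to-end
checks: a 50,000-cell pool with ten root cell types at uneven proportions —
including quiescent-center cells at 0.3% as the hard-to-capture rare
population — 50 markers per type at 10-fold change (identity markers are
strong; droplet studies of root tissue report hundreds of DE genes per
type), five batches standing for five source studies with mild shifts
(`sd 0.15`), and a meristem-to-hair differentiation continuum: trajectory
cells receive a uniform true pseudotime `u` on [0, 1] and their marker
fold-changes interpolate log-linearly between the source and sink profiles,
with labels split at the quantile implied by the two types' proportions.

What the generator does **not** emulate: gene–gene correlation beyond the
type/trajectory structure, doublets, ambient RNA, spliced/unspliced layers,
and zero inflation beyond NB. Passing tests therefore demonstrate that the
machinery measures what it claims on data whose ground truth is known — not
that any particular real tissue saturates at the same sizes.

# Stage-by-stage notes

## Preprocessing

Genes detected in fewer than 3 cells are dropped, then cells with fewer
than 200 expressed genes (one pass, genes first; the operation is
idempotent). Normalisation is `ln(1 + 10^4 x/depth)`. HVG selection ranks
genes by variance-stabilised dispersion: a loess mean–variance trend in
log10 space (span 0.3), z-scores clipped at `sqrt(n)`, top 2000 genes.

Batch structure is handled by per-batch, per-gene mean-centering of the
log-normalised HVG block immediately before PCA. This is a deliberately
simple stand-in for anchor-based integration — adequate for the generator's
multiplicative shifts, not a replacement for CCA on real multi-study data.

## PCA and significant components

PCA operates on per-gene z-scores clipped at ±10, with a sign convention
(dominant loading positive) so results are backend-independent. The solver
is chosen by shape: exact SVD for small problems, a gram-matrix
eigendecomposition when one dimension is ≤ 3000 (the fastest route for
2000 HVGs × tens of thousands of cells on one core), Lanczos otherwise.

`run_pca(regress_depth = TRUE)` residualises each gene against log total
count first. Per-cell normalisation leaves a residual library-size axis
that often ranks among the top PCs; the trajectory recipe removes it
because it competes directly with the differentiation axis.

The JackStraw test permutes a fraction (default 1%) of HVGs across cells,
recomputes the PCA, and pools the permuted genes' squared loadings as the
null per PC. Gene-level empirical p-values use the `(1 + #null ≥ obs) /
(1 + N)` convention, so they are never zero; consequently the gene-level
enrichment threshold defaults to `max(1e-5, 10/(N+1))` — a fixed threshold
below the null's resolution would leave the per-PC binomial test powerless
at any affordable replicate count. The per-PC p-value is a one-sided exact
binomial test that the fraction of genes below the threshold exceeds it;
exactness matters at small gene counts, and the difference from a normal
proportion test is negligible at scale. Significant PCs are counted up to
the first PC at or above `alpha = 0.05`: once one PC fails, later small
p-values are ignored.

## Clustering and agreement

The SNN graph takes each cell's 20 nearest neighbours in 30-PC space
(neighbour sets include the cell), reweights edges by the Jaccard overlap
of neighbour sets and prunes below 1/15; Louvain modularity optimisation at
resolution 1.0 with a fixed seed produces the partition. Cluster IDs are
dense from 0, ordered by size.

Agreement between a subsample's partition and the full-pool reference
(restricted to the subsample's cells) is computed from one pair-count table
`(a, b, c, d)` derived from the contingency table in `O(cells + table)`:

* `RI = (a+d)/C(n,2)`
* `FM = a/sqrt((a+b)(a+c))` (0 if either partition has no co-pair)
* `JI = a/(a+b+c)` (1 if `a+b+c = 0`)
* `HA = [C(n,2)(a+d) − Q]/[C(n,2)² − Q]`, `Q = (a+b)(a+c) + (c+d)(b+d)`
* `MA = [S − E]/[(Sr+Sc)/2 − E]` with `S = Σ n_ij²`, `Sr = Σ n_i·²`,
  `Sc = Σ n_·j²`, `E = Sr·Sc/n²` — the Morey–Agresti chance approximation
  of `E[Σ n_ij²]`.

Degenerate denominators return the documented limits (never NaN); the HA
and MA denominators vanish only for identical trivial partitions, where
both indices are 1. All five are validated in the test suite against an
O(n²) pair-enumeration oracle to 1e-12.

## Annotation

`marker_score` assigns a cluster the type whose markers show the largest
positive mean expression contrast against all other cells, requiring a 10%
relative margin over the runner-up (ties and flat references stay
"unassigned"; assignment is deliberately non-injective). `bulk_spearman`
cross-checks against bulk reference profiles. `ici_assign` implements a
specificity-weighted per-cell identity score, normalised per cell and
damped by the fraction of the type's markers detected, with a bootstrap
null (marker sets resampled from the gene universe) and BH adjustment
across all cell × type pairs. Marker lists and specificity weights are
user inputs; the package ships none.

A type is "discovered" at a ladder size if at least one cluster is assigned
to it. The companion planner `expected_rare_detection(n, p, m_min)` gives
the exact binomial probability of sampling at least `m_min` cells of a type
at frequency `p`; the package's working definition of a *clusterable* rare
population is `m_min = 10` cells captured with 95% probability, the
convention of cell-number planning tools.

## Differential expression

One-vs-rest detection mirrors the standard toolchain filters: detection
fractions (`min.pct = 0.25`), natural-log fold-change of `expm1` means with
pseudocount 1 (threshold 0.25, positive only by default), then a two-sided
Wilcoxon rank-sum on log-normalised values with midranks, tie correction
and continuity correction — numerically identical to
`wilcox.test(exact = FALSE)` (asserted in the tests) but vectorised via
shared rank sums. BH adjustment is per group across tested genes; DEGs are
`q < 0.05` (configurable). The same rank sums give each gene's AUC as a
single-feature classifier (`AUC = (R_in − n_in(n_in+1)/2)/(n_in n_out)`)
and classification power `2|AUC − 0.5|`.

Recovery across the ladder is measured against the nonredundant union of
(gene, type) pairs over all sizes — and, alongside, against the largest
size's set — with AUC distributions split between DEGs common to every size
and DEGs unique to one size.

## Pseudotime

The trajectory stage is a deliberately deterministic stand-in for tree
embeddings: k-means micro-clusters (default 30, at least 10 cells each for
a non-degenerate fit), a minimum spanning tree over the centroids with
Euclidean weights, the root at the centroid richest in the source type
(ties — e.g. several pure-source centroids — resolve to the tree terminus
with the largest eccentricity, so the root cannot land mid-path), and
pseudotime = tree distance from the root plus the cell's projection offset
along its nearest incident edge, shifted to start at 0.

The pipeline recipe `fit_sample_trajectory` subsets the two types,
re-selects HVGs, regresses depth out, and picks the dimensionality by the
scree elbow (at least 2) instead of the global 30 PCs: a one-dimensional
continuum contributes to one or two components, and in the full 30-PC
space 28 noise coordinates dominate centroid distances and let the MST
shortcut across the manifold. Samples smaller than 10 cells per
micro-cluster are flagged `degenerate` — with the default 30 micro-clusters
that is any sample under 300 trajectory cells, which is how 500-cell
ladder draws fail, matching the qualitative instability expected at that
size. Trajectory-dependent genes are found by a Gaussian likelihood-ratio
test of a natural cubic spline (df = 3) of pseudotime against an intercept
model on the log layer (the trajectory consumes the normalised data
without re-standardisation); BH, `q < 0.01`.

## Plateaus and the recommendation

A curve (median over replicate seeds, IQR as dispersion) plateaus at the
smallest size whose value reaches `(1 − ε)` times the value at the largest
size, with `ε = 0.05` by default; if only the largest size qualifies the
plateau is "not reached". Decreases beyond the replicate dispersion
trigger isotonic smoothing first, and the result is flagged. The rule is
monotone in ε. All default metrics (agreement, discovered types, DEG
recovery, significant PCs) increase toward an asymptote; the orientation
is part of the metric declaration. The recommendation is the maximum
plateau over the selected curves — a deliberately conservative reading of
"enough cells for everything measured" — with unreached metrics flagged
rather than silently dropped; if nothing saturates the recommendation is
to enlarge the pool, not a number.

# Replicate ladders for the agreement curve

Neighbouring ladder steps at small sizes (500 vs 1000 cells) differ by
less than the sampling noise of a single draw, so the ordering of a
single-run agreement curve at its low end is partly luck.
`run_config(agreement_replicates = k)` clusters `k` independently seeded
ladders (the reference and all other stages are computed once) and the
agreement curve aggregates replicates by median with IQR dispersion —
the dispersion field the curve container carries for exactly this
purpose. The package's own ladder check uses two replicate ladders.

Two related conventions: the full-pool ladder entry reuses the reference
analysis (re-clustering a permutation of the pool against itself is
trivial), contributes no agreement row, and is excluded from the
DEG-recovery saturation curve, whose asymptote is therefore the largest
proper subsample. The recovery curve that feeds plateau detection tracks
the fraction of the *full-pool* DEG set found at each size; the
union-referenced fraction is reported alongside but is structurally
non-monotone whenever small subsamples over-call (unstable small-sample
clusters generate genuine mixture differences that enter the union as
size-unique DEGs — visible as the declining size-unique counts).

# Problem sizes used in the checks

The package's own end-to-end checks run, by choice, at a reduced but
structurally faithful scale: the 50,000-cell, 3000-gene preset above for
the ladder study; 500 × 1000 pure-noise matrices over 50 seeds with 30
JackStraw replicates for type-I calibration; n = 2000 two-type data for DE
calibration (50 permutations) and power; ten 5000-cell draws for
pseudotime recovery. The analytic oracles (pair enumeration, all-pairs
AUC, binomial tails) run at n ≤ 30–50 where brute force is exact.

# Known limitations

* The integration stand-in is mean-centering; real multi-study pools need
  proper anchor/CCA integration upstream, after which the ladder machinery
  applies unchanged.
* The MST pseudotime handles a two-type, essentially linear continuum; it
  assigns branch states from MST components but is not a general
  branching-trajectory method, and only rank/ordering properties of
  pseudotime are meaningful — the absolute scale depends on the embedding.
* Pair-counting indices are computed exactly with double precision; at
  n ≫ 10⁶ cells the `C(n,2)²` terms would need compensated arithmetic.
* The recommendation policy (max plateau at ε = 0.05) encodes one
  judgement; with several curves a practitioner may reasonably weight
  metrics differently, which is why per-metric plateaus are always
  reported.
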