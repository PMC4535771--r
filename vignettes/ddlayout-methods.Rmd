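---
title: "Methods behind data-driven network layouts"
author: "ddlayout maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind data-driven network layouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddlayout)
library(igraph)
```

# The problem

A biological network — protein–protein interactions, genetic interactions,
the influence graph of a logical model — usually comes with a numerical
vector per node: expression across samples or tissues, epistatic profiles,
stable-state activities. Topology-driven layouts ignore those vectors
entirely, so correlation structure in the data is invisible in the picture.
A *data-driven layout* (DDL) instead places each node at its 2D projection
from the data space, making co-varying nodes spatial neighbours. This
vignette describes the models implemented in `ddlayout`, the parameters
that matter, and the numerical choices taken where the design was open.

# Pre-processing the data matrix

## Missing-value filtering

Rows (nodes) with strictly more than `maxMissingFraction` missing entries
(default 0.20) are dropped before any projection. The comparison is strict:
a 10-sample profile with 2 missing entries (20 %) is kept, one with 3
(30 %) is dropped. Dropped nodes are not lost from the picture — they are
placed from their network neighbours at the layout stage (see below).

## Double-centering

`doubleCenter` subtracts each entry's row mean and column mean and adds
back the grand mean. For a complete matrix the result has exactly zero row
and column means, and the operation is idempotent (it is the orthogonal
projector onto the doubly-centered subspace). It removes additive per-node
and per-sample offsets — probe-intensity or library-size style biases —
that would otherwise dominate the first principal component. Means are
computed over observed cells only, and missing cells remain missing.

## Network smoothing

Let `L = D − A` be the unnormalized Laplacian of the (undirected, simple)
network, with eigenvalues `0 = λ₁ ≤ … ≤ λ_N` and orthonormal eigenvectors
`v₁ … v_N`. Exactly `n_c` eigenvalues are zero, one per connected
component, and their eigenspace is spanned by the component indicator
vectors; eigenvectors of small positive eigenvalue vary slowly along edges.
Smoothing replaces each data column `c` by its projection
`Σ_{i≤k} ⟨c, v_i⟩ v_i` onto the span of the first `k` eigenvectors,
attenuating variation that disagrees with the network.

Rather than exposing `k` directly, the strength is parameterized as

$$p_{ns} = 1 - \frac{k - (n_c + 2)}{N - (n_c + 2)}, \qquad p_{ns} \in [0, 1],$$

so `p_ns = 0` keeps all `N` eigenvectors (the projector is the identity —
no smoothing) and `p_ns = 1` keeps `k = n_c + 2`: the component indicators
plus the two smoothest non-degenerate eigenvectors. At maximal smoothing
the data matrix therefore has rank at most `n_c + 2` — rank 3 on a
connected graph — with the component-indicator direction carrying each
component's average value. Because the formula rarely gives an integer,
`k` is rounded half-up and clamped to `[n_c + 2, N]`; on graphs so small
that `N ≤ n_c + 2` the parameterization is undefined and `k = N` is used
with a warning.

Two properties follow from the construction and are enforced by tests: the
smoothing operator `V_k V_kᵀ` is a symmetric idempotent projector with
eigenvalues in {0, 1}, and smoothed column norms never exceed the input's.

The operator needs one matrix row per graph node, so the end-to-end
pipeline smooths on the subgraph induced by the nodes that retain data.
Rows must be complete at this point; missing entries surviving the filter
are imputed with the row's observed mean first (with a warning). When both
double-centering and smoothing are requested, centering is applied first:
both maps are linear so the choice is a convention, but centering is data
cleaning while smoothing is network regularization, and cleaning precedes
regularization. Both orders remain reachable through the individual
functions.

The full eigendecomposition is `O(N³)`; for reuse across datasets
`saveBasis`/`loadBasis` cache it in a plain-text container together with a
fingerprint of the graph (an FNV-1a hash over the sorted node and edge
lists). The loader re-validates orthonormality and refuses a cache whose
fingerprint does not match the graph it is asked to serve.

# Dimension reduction

## PCA with missing values

Principal components are estimated without imputation by alternating least
squares over observed cells: the model
`x_ij ≈ m_j + Σ_l u_il v_jl` is fitted one component at a time, the rank-1
NIPALS iteration restricted to observed entries, each converged component
deflated from the residual before the next. Convergence is declared when
the unit-norm loading vector changes by less than `1e-9` between
iterations (the iteration cap, 20 000 by default, exists because trailing
components of nearly isotropic data have tiny eigenvalue gaps and the
power-type iteration is then slow; hitting the cap is an error, not a
silent stop). On complete data the scores equal classical SVD scores up to
per-component sign; each component is oriented so its largest-magnitude
loading is positive, making results reproducible across solvers.

Ten components are computed when there are more than ten data points, and
`n − 1` otherwise. Variance explained per component is the reduction in
observed-cell residual sum of squares divided by the total centered sum of
squares; components are reported in decreasing order of that fraction
(with missing data the extraction order can invert neighbouring
components).

## Elastic-map principal manifolds

The nonlinear option fits a rectangular grid of nodes `y_1 … y_g` in data
space by minimizing the elastic energy

$$U = \sum_i \lVert x_i - y_{k(i)} \rVert^2
    + \lambda \sum_{\text{edges}} \lVert y_a - y_b \rVert^2
    + \mu \sum_{\text{ribs}} \lVert y_a - 2 y_b + y_c \rVert^2,$$

where `k(i)` is the grid node nearest to `x_i`, edges are grid adjacencies
and ribs are consecutive collinear node triples. Fitting alternates (1)
nearest-node assignment and (2) an exact linear solve for all grid
positions given the assignment — each step cannot increase `U`, so the
energy is non-increasing within an epoch (asserted by tests). The
coefficients are annealed from stiff to soft; the default schedule,
`(λ, μ)` = (1, 10) → (0.1, 1) → (0.01, 0.1) with 20 iterations each on a
12 × 12 grid, lets the grid first settle into the global orientation and
then bend into the data. The grid is initialized on the plane of the first
two principal components spanning the data, which also makes the fit
deterministic. In the stiff limit (large `μ`, a bending penalty that is
zero exactly for affine grids) the manifold stays planar and reproduces
the PCA plane — a limit the tests verify by Procrustes residual. The
published description of the original tool does not state its elasticity
coefficients or grid size, so these defaults are this package's own and
are fully exposed through `elasticMapConfig`.

A fitted point's 2D coordinate is its piecewise-linear projection onto the
manifold (each grid cell split into two triangles; closest clamped
projection wins), expressed in internal grid coordinates scaled by the
initial grid spacing so they are commensurate with PCA scores. Variance
explained is `1 − RSS/TSS` with residuals to the projection point — not to
the nearest grid node, which would understate the manifold's fit. Missing
entries are handled without imputation: assignments, solves and
projections use observed coordinates only, weighted by the ratio of total
to observed dimensions.

# From projection to layout

Three post-processing steps, in order:

1. **Overlap jitter.** Nodes closer than `overlapEpsilon` (default 1e-3)
   times the bounding-box diagonal — e.g. nodes with identical profiles —
   are displaced by `jitterRadius` (default 5e-3) × diagonal in a random
   direction from a dedicated seeded generator, so package calls never
   disturb the caller's RNG state and never move a node farther than the
   jitter radius. Scaling by the diagonal makes behaviour invariant to
   layout units.
2. **Outlier pull-in.** A node whose distance to the barycenter exceeds
   `outlierFactor` (default 6) times the median distance-to-barycenter is
   moved along the ray to the barycenter until its distance equals that
   threshold. The median makes the threshold robust; a single pass is
   applied, and because a moved outlier shifts the barycenter slightly, a
   second application is a contraction of the same nodes rather than an
   exact no-op.
3. **Placement of filtered nodes.** Nodes excluded for missing data are
   placed at the mean position of their already-placed network neighbours,
   iterated Jacobi-style (each pass uses only the previous pass's
   positions, so the result is order-independent) until stable; nodes in
   fully-excluded or isolated regions fall back to the barycenter of the
   placed nodes.

# Morphing, alignment and layout quality

Morphing is node-wise linear interpolation
`p·x_target + (1−p)·x_initial`; endpoints reproduce the inputs exactly and
every node's trajectory is a straight line. Because a DDL is arbitrary up
to rotation and reflection, morphing against a structure-driven layout is
meaningful only after alignment: `alignLayouts` solves the 2D orthogonal
Procrustes problem in closed form, evaluating both reflection branches and
keeping the smaller residual. No scaling is applied — the original method
lists rotation and mirroring only, and preserving scale keeps morphing
distances meaningful. Centroids of the shared nodes are matched before
rotation; rotation about an unspecified origin would be ill-defined, and
centroid matching is the standard Procrustes convention, documented here
as this package's choice rather than claimed identical to the original
tool.

Layout quality (QDM) is the Pearson correlation between data-space and
layout distances over representative pairs chosen by farthest-point
sampling: the globally most distant pair first, then repeatedly the point
maximizing its minimum distance to the selected set, each contributing the
pair (new point, nearest selected point). Ties break by sorted node ID, so
selection is deterministic. The default sample is `min(n, 100)` points
(the original publication does not state a count), and an `allPairs`
variant correlating over all pairs among the selected points is available
because the construction in the cited methodology admits both readings.
The statistic is invariant under rigid transforms of the layout, and
p-values come from the usual t distribution via `stats::cor.test`.

# The synthetic fixture

`generateFixture` emulates the modular tissue-network setting at desk
scale: a planted-partition graph (`pWithin = 0.3`, `pBetween = 0.02` by
default — sparse modules with occasional cross-links) whose clusters carry
block-structured expression signatures (`effect = 3`, `noiseSd = 1`, i.e.
a 3-sigma shift of a cluster in its own block of samples), with optional
uniform random cell deletion. It reproduces the features the method needs
— modular topology aligned with data-space clusters, missingness — but not
the properties of real omics data: heavy-tailed expression, correlated
missingness, hub-dominated degree distributions, or batch structure.
Passing tests on fixture data therefore demonstrate correctness of the
algorithms, not performance claims on any particular biological dataset;
the published case-study numbers depend on external cohort data and are
out of scope here. Test and acceptance problem sizes (tens of nodes,
hundreds at most, ≤ 20 samples) were chosen as the smallest at which each
property is non-trivially exercised.

# Degenerate inputs and tie-breaking

* Eigenvalue ties in the Laplacian make individual eigenvectors
  solver-dependent; every contract is stated on the projector (the span),
  never on individual tied eigenvectors.
* `smoothMatrix` accepts `k ≥ n_c` rather than `n_c + 2` so
  component-constant columns can be shown invariant at the smallest
  sensible subspace.
* Graphs with `N ≤ n_c + 2` ignore `p_ns` (with a warning) since the
  parameterization is undefined there.
* All-identical data points are an error for the elastic map and for
  representative-pair selection ("degenerate distances"); an all-coincident
  source layout yields a translation-only alignment with a warning.
* SIF relation types are ignored for topology; self-loops and duplicate
  edges are dropped; node IDs are case-sensitive exact strings, and matrix
  rows without a network node are dropped with a warning (the behaviour of
  the original tool for such rows is undocumented; dropping loudly is this
  package's choice).

# Known limitations

* Only the unnormalized Laplacian is supported; normalized and random-walk
  variants change the meaning of `p_ns` and are out of scope.
* Full dense eigendecomposition limits smoothing to networks of a few
  thousand nodes on desktop hardware; the basis cache mitigates repeated
  analyses of the same network.
* Elastic-map defaults are not claimed to match the original Java
  implementation's unpublished constants; treat cross-tool coordinate
  comparisons accordingly.
* Layouts are 2D only; 3D and multidimensional-scaling embeddings are
  deliberately not implemented.
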