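---
title: "Topographic maps of high-dimensional structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic maps of high-dimensional structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A 2-D scatter plot produced by a dimensionality-reduction method (PCA,
t-SNE, UMAP, MDS, ...) cannot in general preserve the distances of the
high-dimensional data it depicts: some pairs of points that are far apart in
the input space will land close together on paper, and cluster borders can
vanish or appear out of nothing. `toposom` takes the original data *and* its
2-D projection and builds a third artifact — a topographic map — that shows,
on top of the projection's layout, the *true* high-dimensional distance
structure: valleys are clusters, mountain ranges are cluster borders, and a
point placed next to points it is actually far away from sits on a volcano.

The machinery is a simplified emergent self-organizing map (sESOM) combined
with the generalized U-matrix. "Emergent" means the lattice is large
(thousands of neurons, far more than data points), so the map acts as a
quasi-continuous projection surface rather than a clustering.

## The procedure

Given data $X = \{x_1,\dots,x_n\} \subset \mathbb{R}^d$ and a projection
$p_1,\dots,p_n \in \mathbb{R}^2$:

1. **Lattice sizing.** A toroidal lattice of $L$ lines by $C$ columns is
   chosen so that (I) its shape matches the projection's bounding box,
   $(L-1)/(C-1) \approx \Delta = \mathrm{extent}_y/\mathrm{extent}_x$, and
   (II) it has at least $NN = \max(n, \text{emergence floor})$ neurons.
   Substituting (I) into (II) gives the quadratic condition
   $L^2 + L(1+\Delta) - NN\,\Delta \ge 0$, i.e.
   $L \ge -\tfrac{1+\Delta}{2} + \sqrt{\left(\tfrac{1+\Delta}{2}\right)^2 +
   NN\,\Delta}$. We take the ceiling for $L$, set
   $C = \mathrm{round}((L-1)/\Delta)+1$, and bump $C$ until
   $L\cdot C \ge NN$.

2. **BMU fixing (`fgrid`).** Each projected point is mapped affinely onto a
   lattice cell: $\min(x) \to$ column 1, $\max(x) \to$ column $C$,
   $\max(y) \to$ line 1, $\min(y) \to$ line $L$ (image row order), with
   round-half-up and clamping. These cells are the points' best-matching
   units; several points may share a cell.

3. **sESOM training.** The only schedule is a radius cooling from
   $R_{\max} = C/6$ down to 1 in unit steps — no learning rate, no epoch
   count. The neighbourhood kernel is
   $h(d, R) = 1 - d^2/(\pi R^2)$ when $d^2 < \pi R^2$ and 0 otherwise,
   where $d$ is the minimum-image (toroidal) Euclidean grid distance to the
   BMU. Each radius step presents every point once in seeded-shuffled
   order; the BMU is re-searched globally over all prototypes
   ($\mathrm{bmu}(x) = \arg\min_i D(x, w_i)$), and all prototypes within the
   kernel's support move by $w \leftarrow w + h\,(x - w)$; the BMU cell
   itself becomes $x$ exactly. After every radius step the prototypes of
   cells that own projected points are reset to (the mean of) their points,
   so the projection's layout anchors the map throughout.

4. **Generalized U-matrix.** For each cell $j$, the U-height is
   $u(j) = \tfrac{1}{8}\sum_{i \in N(j)} D(w_i, w_j)$ over its eight
   toroidal Moore neighbours. Low heights mean the surrounding prototypes
   are close in input space (cluster interior); high heights mean a border.

5. **Topographic rendering.** Heights are robustly normalized by the 1st
   and 99th percentiles, $u' = (u - q_{01})/(q_{99} - q_{01})$, clamped to
   $[0,1]$; the number of elevation classes is
   $\lceil q_{99}/q_{01} \rceil$ clamped into $[8, 64]$; classes are
   coloured by CIELab interpolation of a hypsometric ramp (blue sea, green
   and brown hills, white peaks); region boundaries are traced as contours;
   the toroidal map is tiled $2 \times 2$ so every receptive field appears
   four times; and an island is cut automatically (see below).

6. **Valley counting.** The toroidal map is thresholded at a sea level
   (default 0.3); 8-connected low components holding at least a minimum
   share of the projected points are counted as valleys, i.e. clusters.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `emergence_floor` | 4096 | minimum neuron count. Emergence needs thousands of neurons (more than 4000); 4096 = 64² gives a clean square default when the floor dominates. |
| `seed` | 1 | run seed for prototype initialization and presentation shuffling; a fixed seed makes a run bit-reproducible. |
| `metric` | Euclidean | input-space distance $D$ for BMU search and U-heights (Manhattan also available). The same $D$ is used in both places. |
| `sea_level` | 0.3 | valley threshold on normalized heights, chosen so the blue (sea) classes of the default ramp coincide with valleys. |
| `min_share` | 0.05 | fraction of the data a low component must hold to count as a valley (see below). |

The training loop itself is deliberately parameter-free: radius schedule
and lattice size are derived, and there is no learning rate.

## Design decisions

**Lattice rounding.** The sizing conditions are inequalities; we return the
smallest lattice satisfying both, with $L, C \ge 3$ enforced because the
Moore neighbourhood is undefined below that.

**Interval-count reading.** The percentile ratio that sets the number of
elevation classes is taken as $q_{99}/q_{01}$ (more classes when heights
span a wide dynamic range), with clamps $[8, 64]$ absorbing degenerate
percentiles. The opposite reading ($q_{01}/q_{99} < 1$) cannot yield a
count of intervals.

**Initialization.** Prototypes of unoccupied cells are initialized to data
points sampled uniformly under the run seed: this keeps every prototype
inside the data's support and avoids scale pathologies of random-coordinate
initialization. Occupied cells start (and end) at the mean of their points —
the mean being the symmetric choice when `fgrid` collisions put several
points into one cell.

**Presentation order.** A fresh seeded shuffle per radius step, following
online-SOM convention; sequential order would imprint the storage order of
the data onto the map.

**Valley significance (`min_share`).** Robust normalization stretches even
a structure-free map across the full $[0,1]$ range — that is its purpose —
so after thresholding, a noisy terrain always contains a few one- or
two-cell ponds holding a point or two. Counting those as clusters would be
wrong in exactly the cases the map is supposed to get right: tiny groups
far from everything are outlier peaks (volcanoes), not clusters. A valley
therefore must hold at least `min_share` (default 5%) of the projected
points. The default is deliberately below any equal-sized cluster share for
realistic $k$ while well above single-point noise.

**Automatic island cut.** The interactive step of cutting an island out of
the tiled display is replaced by an exhaustive search over all $L \cdot C$
cyclic shifts for the window whose border crosses the highest total
terrain: cuts go through mountains, valleys stay whole. Every cell appears
exactly once in any such window, so no BMU can be lost. Ties resolve to the
lexicographically smallest shift, making the result deterministic.

**Contours.** Boundaries between maximal same-class regions
(8-connectivity) are chained from cell-edge segments on the tiled,
non-wrapping view. Chains close into loops around interior regions; chains
that run into the border of the tiled array remain open. The outer border
itself is not outlined, so a uniform map has no contours.

**Gaussian-mixture testbed.** Cluster centres are placed on a regular
simplex with *all* pairwise distances equal to `separation` (for
$k \le d$): if one pair of centres were several times farther apart than
another, the wide pair's ridge would dominate $q_{99}$ and the close pair's
ridge would normalize below sea level — the parameter would no longer
control the separation it names. The default within-cluster noise is
$\sigma = 0.05$ with separation 5: compact, well-separated clusters, the
regime in which a cluster count is well defined at all.

## What the synthetic fixtures emulate — and what they do not

- **Chainlink**: two interlocked unit rings in orthogonal planes; linearly
  non-separable, and any linear projection must place some cross-ring
  points adjacently. This reproduces the canonical projection-error
  scenario: the map shows a mountain ridge between projected neighbours
  that are far apart in 3-D.
- **Bars-plus-outliers** (`make_lsun3d_like`): three clusters of different
  shape plus exactly four distant outliers; outliers should appear as
  isolated peaks, not valleys. The generator is structurally equivalent to,
  but not numerically identical with, the classic benchmark of the same
  shape — hence the "-like" suffix.
- **Golfball**: uniform points on a sphere surface — no distance structure.
  Its map should show at most one percolating sea and a much smaller raw
  height dynamic range ($q_{99}/q_{01}$) than clustered data.
- **Gaussian mixtures**: the controlled-separation testbed.

Passing tests on these fixtures show that the pipeline recovers *known,
geometrically clean* structure at moderate $n$ (hundreds of points, $d = 3$)
and flags its absence. They do not show robustness to the features of real
omics embeddings — thousands of dimensions, heavy-tailed noise, unequal
cluster sizes and densities, or nonlinear projections with their own
artifacts. For such data the map remains an exploratory instrument; the
valley count at a fixed sea level is a summary, not an inference.

## Numerical choices

- Percentiles use linear interpolation between order statistics
  (R's default type 7); percentile conventions differ between libraries, so
  this is stated explicitly.
- The kernel's case split $d^2/(\pi R^2) < 1$ is evaluated on the squared
  grid distance directly; the boundary case belongs to the zero branch.
- BMU ties break to the smallest (line, column) lexicographically, making
  training deterministic given the seed.
- Degenerate inputs: a projection with zero extent in one axis maps all
  points to the middle line/column instead of erroring (matching the
  $\Delta = 1$ guard of the aspect ratio), and constant U-matrices
  normalize to an all-zero map.
- The training inner loop is compiled (Rcpp); an R-level reference loop
  built from the exported single-step operations is kept under test to
  guarantee the two routes agree to within $10^{-12}$.

## Problem sizes used by the test suite

The structure-recovery suites run the full pipeline on $n = 900$ (3-cluster
mixture) and $n = 500$ (golfball, chainlink) over 10 seeds each on a
roughly $64 \times 64$ lattice, sizes at which the compiled training loop
takes a few seconds per run; oracle comparisons for the U-matrix use
exhaustive small lattices up to $8 \times 8$. These sizes are the package's
own test design; the pipeline itself has no size limits beyond memory.

## Known limitations

- The valley count depends on `sea_level` and `min_share`; clusters that
  merge gradually (chains, overlapping Gaussians) produce shallow
  watersheds that a fixed threshold may miss.
- U-heights are distance-based only; no density estimate enters the map, so
  density-based structure that leaves distances unchanged is invisible.
- The island cut optimizes border height only; for maps with several
  disjoint mountain systems, other aesthetic criteria (centering the
  largest valley, say) are not considered.
- `fgrid` keeps collisions; extremely low-resolution projections (many
  points per cell) blur the map because cell means stand in for points.

## A worked call

```{r, eval = FALSE}
library(toposom)

ds <- make_gaussian_mixture(k = 3, n = 900, d = 3, separation = 5, seed = 42)
proj <- make_linear_projection(ds$data)
gu <- generalized_umatrix(ds$data, proj, labels = ds$labels, seed = 42)

glance(gu)        # lattice, percentiles, valley count
tidy(gu)          # one row per cell: height, class, colour
autoplot(gu)      # tiled topographic map with contours and points
autoplot(gu, island = TRUE)
```
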