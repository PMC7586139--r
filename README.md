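# toposom

Topographic maps of high-dimensional structure from 2-D projections.

## What problem does this solve?

Dimensionality-reduction methods (PCA, t-SNE, UMAP, MDS, ...) compress
high-dimensional data — biomarker panels, omics profiles, single-cell
embeddings — into 2-D scatter plots. Such plots *cannot* faithfully
represent high-dimensional distances: points that are far apart in the data
can land side by side on paper, and real cluster borders can disappear.
Anyone who reads cluster structure off a scatter plot needs a way to check
what the projection distorted.

`toposom` builds that check. It trains a **simplified emergent
self-organizing map (sESOM)** on a large toroidal lattice, with each data
point's best-matching unit (BMU) pinned to the lattice cell its projected
coordinates fall on, and then computes the **generalized U-matrix**: for
every lattice cell $j$ with prototype $w_j$, the U-height

$$u(j) = \frac{1}{8}\sum_{i \in N(j)} D(w_i, w_j)$$

over its eight toroidal neighbours. Rendered with hypsometric tints, the
result reads like a topographic map of the projection:

- **valleys** (blue) are clusters in the *high-dimensional* data,
- **mountain ranges** (brown/white) are cluster borders,
- a point sitting on a **volcano** was placed next to points it is actually
  far away from — a projection error made visible,
- the number of valleys containing points estimates the number of clusters,
- a map with no valleys reveals the *absence* of distance-based structure.

Training is parameter-free: the lattice size follows from the projection's
bounding box and the number of points (with an emergence floor of 4096
neurons), the radius schedule cools from $C/6$ down to 1 in unit steps with
the kernel $h = 1 - d^2/(\pi R^2)$, and there is no learning rate or epoch
count. Only the run seed and the distance metric are configurable.

## A worked example

```r
library(toposom)

# three tight Gaussian clusters in 3-D, plus their PCA projection
ds   <- make_gaussian_mixture(k = 3, n = 900, d = 3, separation = 5, seed = 42)
proj <- make_linear_projection(ds$data)

gu <- generalized_umatrix(ds$data, proj, labels = ds$labels, seed = 42)
gu
#> <generalized_umatrix> trained with seed 42 (euclidean metric)
#> <topographic_map> 61 x 68 lattice, 64 elevation classes
#>   height percentiles q01 = 0.0068, q99 = 2.123
#>   valleys (clusters) at sea level 0.30: 3

glance(gu)
#> # A tibble: 1 x 9
#>       L     C n_neurons n_points n_intervals     q01   q99 sea_level n_valleys
#>   <int> <int>     <int>    <int>       <int>   <dbl> <dbl>     <dbl>     <int>
#> 1    61    68      4148      900          64 0.00680  2.12       0.3         3
```

What the numbers mean: the projection's bounding box and the 900 points
produced a 61 × 68 toroidal lattice (4148 neurons, above the 4096
emergence floor). The U-heights span a wide dynamic range
(q99/q01 ≈ 312, hence the maximum 64 elevation classes) — the signature of
strong distance structure — and thresholding the normalized map at sea
level 0.3 finds exactly 3 valleys holding points: the correct cluster
count. On the structure-free golfball benchmark the same call yields a
single percolating sea (≤ 1 valley) and a dynamic range an order of
magnitude smaller.

```r
tidy(gu)                    # one row per lattice cell: height, class, colour
autoplot(gu)                # 2L x 2C tiled map: contours, points, tints
autoplot(gu, island = TRUE) # automatically cut L x C island
render_topographic_map(gu, "map.png")
```

Benchmark generators: `make_chainlink()` (interlocked rings — linearly
non-separable, the classic projection-error case), `make_lsun3d_like()`
(3 clusters + 4 outliers), `make_golfball()` (uniform sphere surface, no
structure), `make_gaussian_mixture()` (controlled separation). A
command-line front end over the same functions is installed at
`inst/cli/gumatrix.R` (subcommands `compute`, `synth`, `valleys`).

## Scope

The projection method itself is an *input*: this package evaluates
projections, it does not produce them (`make_linear_projection()` is only a
PCA convenience fixture). Density-weighted map variants and interactive
island editing are out of scope; the island cut is automatic
(border-height maximization over all cyclic shifts).

See `vignettes/topographic-maps.Rmd` for the full method description,
parameter rationale, and known limitations.
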