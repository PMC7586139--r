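#' Build a topographic map from a U-matrix
#'
#' Combines the rendering stages: robust normalization of the U-heights,
#' derivation of the number of elevation intervals from the height
#' percentiles, hypsometric colorization, 2 x 2 toroidal tiling, contour
#' extraction on the tiled view, automatic island cut-out, and valley
#' counting.
#'
#' @param umatrix An `esom_umatrix` from [compute_uheights()].
#' @param bmus A `bmu_assignment`; needed for valley counting and for
#'   drawing the projected points.
#' @param labels Optional integer/factor vector of point labels (colours of
#'   the BMU markers).
#' @param scale A [hypsometric_scale()].
#' @param sea_level Valley threshold, see [count_valleys()].
#' @return An object of class `topographic_map` with elements `normalized`,
#'   `class`, `colors`, `tiled` (list of tiled height/class matrices),
#'   `contours`, `island`, `n_valleys`, `n_intervals`, `q01`, `q99`,
#'   `lattice`, `bmus`, `labels`, `sea_level`.
#' @export
topographic_map <- function(umatrix, bmus, labels = NULL,
                            scale = hypsometric_scale(), sea_level = 0.3) {
  stopifnot(inherits(umatrix, "esom_umatrix"),
            inherits(bmus, "bmu_assignment"))
  if (!is.null(labels) &&
      length(labels) != nrow(bmus$positions)) {
    stop("labels must have one entry per data point", call. = FALSE)
  }
  norm <- robust_normalize(umatrix)
  q01 <- attr(norm, "q01"); q99 <- attr(norm, "q99")
  n_int <- interval_count(q01, q99)
  col <- colorize(norm, scale, n_int)
  tiled_heights <- tile_toroidal(norm)
  tiled_class <- tile_toroidal(col$class)
  structure(list(
    normalized  = norm,
    class       = col$class,
    colors      = col$colors,
    tiled       = list(heights = tiled_heights, class = tiled_class),
    contours    = extract_contours(tiled_class),
    island      = cut_island(norm, bmus),
    n_valleys   = count_valleys(norm, bmus, sea_level),
    n_intervals = n_int,
    q01 = q01, q99 = q99,
    lattice = umatrix$lattice,
    bmus = bmus, labels = labels,
    sea_level = sea_level
  ), class = "topographic_map")
}

#' @export
print.topographic_map <- function(x, ...) {
  cat(sprintf(paste0(
    "<topographic_map> %d x %d lattice, %d elevation classes\n",
    "  height percentiles q01 = %.4g, q99 = %.4g\n",
    "  valleys (clusters) at sea level %.2f: %d\n"),
    x$lattice$L, x$lattice$C, x$n_intervals, x$q01, x$q99,
    x$sea_level, x$n_valleys))
  invisible(x)
}

#' Generalized U-matrix pipeline
#'
#' One call from data + projection to topographic map: sizes the toroidal
#' lattice from the projection's bounding box and the number of points, fixes
#' the best-matching units with the grid transform, trains the simplified
#' emergent SOM, computes the U-heights and renders them as a topographic
#' map. If no projection is supplied, the first two principal components of
#' the data are used.
#'
#' @param data Numeric n x d matrix or data frame (rows = points).
#' @param projection Optional n x 2 matrix/data frame of projected
#'   coordinates from any dimensionality-reduction method.
#' @param labels Optional per-point labels for display.
#' @param seed Run seed (initialization and presentation shuffling).
#' @param metric Input-space distance, `"euclidean"` or `"manhattan"`.
#' @param emergence_floor Minimum neuron count, see [size_lattice()].
#' @param sea_level Valley threshold, see [count_valleys()].
#' @param scale Colour scale, see [hypsometric_scale()].
#' @return An object of class `generalized_umatrix`: a `topographic_map`
#'   plus elements `umatrix`, `grid`, `config`.
#' @examples
#' \donttest{
#' set.seed(1)
#' ds <- make_gaussian_mixture(k = 3, n = 300, d = 3, separation = 5, seed = 1)
#' gu <- generalized_umatrix(ds$data, make_linear_projection(ds$data),
#'                           labels = ds$labels, seed = 1)
#' gu$n_valleys
#' }
#' @export
generalized_umatrix <- function(data, projection = NULL, labels = NULL,
                                seed = 1L,
                                metric = c("euclidean", "manhattan"),
                                emergence_floor = 4096, sea_level = 0.3,
                                scale = hypsometric_scale()) {
  metric <- match.arg(metric)
  X <- as_data_matrix(data)
  if (is.null(projection)) projection <- make_linear_projection(X)
  xy <- as_projection_matrix(projection)
  if (nrow(xy) != nrow(X)) {
    stop("projection must have one row per data point", call. = FALSE)
  }
  delta <- compute_aspect_ratio(xy)
  lattice <- size_lattice(delta, nrow(X), emergence_floor)
  bmus <- map_projection_to_grid(xy, lattice)
  config <- sesom_config(seed = seed, metric = metric)
  grid <- train_sesom(X, bmus, lattice, config)
  umx <- compute_uheights(grid, metric)
  tm <- topographic_map(umx, bmus, labels = labels, scale = scale,
                        sea_level = sea_level)
  tm$umatrix <- umx
  tm$grid <- grid
  tm$config <- config
  class(tm) <- c("generalized_umatrix", "topographic_map")
  tm
}

#' @export
print.generalized_umatrix <- function(x, ...) {
  cat(sprintf("<generalized_umatrix> trained with seed %d (%s metric)\n",
              x$config$seed, x$config$metric))
  NextMethod()
}

#' Tidy a topographic map into one row per lattice cell
#'
#' @param x A `topographic_map` (or `generalized_umatrix`).
#' @param ... Unused.
#' @return Tibble with columns `line`, `column`, `height` (normalized),
#'   `class` (elevation class) and `color`.
#' @export
tidy.topographic_map <- function(x, ...) {
  grid_tibble(x$normalized, "height") |>
    dplyr::mutate(class = as.vector(t(x$class)),
                  color = x$colors[.data$class])
}

#' One-row summary of a topographic map
#'
#' @param x A `topographic_map` (or `generalized_umatrix`).
#' @param ... Unused.
#' @return Tibble with `L`, `C`, `n_neurons`, `n_points`, `n_intervals`,
#'   `q01`, `q99`, `sea_level`, `n_valleys`.
#' @export
glance.topographic_map <- function(x, ...) {
  tibble::tibble(
    L = x$lattice$L, C = x$lattice$C,
    n_neurons = x$lattice$L * x$lattice$C,
    n_points = nrow(x$bmus$positions),
    n_intervals = x$n_intervals,
    q01 = x$q01, q99 = x$q99,
    sea_level = x$sea_level,
    n_valleys = x$n_valleys
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
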