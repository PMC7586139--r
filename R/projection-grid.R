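#' Map projected points onto fixed lattice cells (fgrid)
#'
#' The deterministic transform from scatter-plot coordinates to best-matching
#' units: x is affinely rescaled so that `min(x)` lands on column 1 and
#' `max(x)` on column C; y so that `max(y)` lands on line 1 and `min(y)` on
#' line L (the y axis runs from line L at the bottom up to line 1 at the top,
#' matching image row order). Fractional coordinates are rounded half-up and
#' clamped into bounds. Several points may share a cell; such collisions are
#' retained and recorded.
#'
#' @param projection Data frame or matrix, n rows, first two columns = (x, y).
#' @param lattice An [esom_lattice()].
#' @return An object of class `bmu_assignment`: list with
#'   * `positions`: tibble with columns `point`, `line`, `column`, `cell`
#'     (row-major cell index), one row per data point;
#'   * `lattice`: the lattice.
#' @examples
#' lat <- esom_lattice(65, 65)
#' pr <- cbind(x = c(0, 1, 0.5), y = c(0, 1, 0.5))
#' map_projection_to_grid(pr, lat)$positions
#' @export
map_projection_to_grid <- function(projection, lattice) {
  xy <- as_projection_matrix(projection)
  if (!inherits(lattice, "esom_lattice")) {
    stop("`lattice` must be an esom_lattice", call. = FALSE)
  }
  n <- nrow(xy)
  if (n < 1L) stop("projection must contain at least 1 point", call. = FALSE)

  column <- scale_axis(xy[, 1], lattice$C, flip = FALSE)
  line   <- scale_axis(xy[, 2], lattice$L, flip = TRUE)

  positions <- tibble::tibble(
    point  = seq_len(n),
    line   = line,
    column = column,
    cell   = cell_index(line, column, lattice)
  )
  structure(list(positions = positions, lattice = lattice),
            class = "bmu_assignment")
}

#' @export
print.bmu_assignment <- function(x, ...) {
  cat(sprintf("<bmu_assignment> %d points on %d x %d lattice (%d occupied cells)\n",
              nrow(x$positions), x$lattice$L, x$lattice$C,
              dplyr::n_distinct(x$positions$cell)))
  invisible(x)
}

#' Members of each occupied lattice cell
#'
#' @param bmus A `bmu_assignment`.
#' @return A tibble with one row per occupied cell: `cell`, `line`, `column`,
#'   `n_points`, and a list-column `points` of the data-point indices assigned
#'   there.
#' @export
cell_members <- function(bmus) {
  stopifnot(inherits(bmus, "bmu_assignment"))
  bmus$positions |>
    dplyr::group_by(.data$cell, .data$line, .data$column) |>
    dplyr::summarise(n_points = dplyr::n(),
                     points = list(.data$point), .groups = "drop") |>
    dplyr::arrange(.data$cell)
}

# affine map of one projection axis onto 1..extent; flip = TRUE reverses
# orientation (large values -> line 1). Degenerate extent -> middle index.
scale_axis <- function(v, extent, flip) {
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi)) {
    stop("projection coordinates must be finite", call. = FALSE)
  }
  if (hi - lo < 1e-12) {
    return(rep(round_half_up((1 + extent) / 2), length(v)))
  }
  t <- (v - lo) / (hi - lo)
  if (flip) t <- 1 - t
  idx <- round_half_up(1 + t * (extent - 1))
  pmin.int(pmax.int(idx, 1L), extent)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

# accept matrix / data frame, take first two numeric columns
as_projection_matrix <- function(projection) {
  if (is.data.frame(projection)) projection <- as.matrix(projection)
  if (!is.matrix(projection) || !is.numeric(projection) ||
      ncol(projection) < 2L) {
    stop("projection must be an n x 2 numeric matrix or data frame",
         call. = FALSE)
  }
  projection[, 1:2, drop = FALSE]
}
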