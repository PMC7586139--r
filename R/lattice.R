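#' Toroidal lattice constructor
#'
#' A lattice of `L` lines by `C` columns whose opposite borders are cyclically
#' connected, so that every cell has exactly eight Moore neighbours and no
#' border effects exist. All maps in this package live on such a torus.
#'
#' @param L Number of lines (rows), integer >= 3.
#' @param C Number of columns, integer >= 3.
#' @return An object of class `esom_lattice`: a list with elements `L`, `C`
#'   and `toroidal = TRUE`.
#' @examples
#' esom_lattice(64, 64)
#' @export
esom_lattice <- function(L, C) {
  L <- as.integer(L)
  C <- as.integer(C)
  if (length(L) != 1L || length(C) != 1L || is.na(L) || is.na(C)) {
    stop("`L` and `C` must be single integers", call. = FALSE)
  }
  if (L < 3L || C < 3L) {
    stop("lattice must be at least 3 x 3 (Moore neighbourhood undefined below)",
         call. = FALSE)
  }
  structure(list(L = L, C = C, toroidal = TRUE), class = "esom_lattice")
}

#' @export
print.esom_lattice <- function(x, ...) {
  cat(sprintf("<esom_lattice> toroidal %d lines x %d columns (%d neurons)\n",
              x$L, x$C, x$L * x$C))
  invisible(x)
}

#' Aspect ratio of a 2-D projection's bounding box
#'
#' The ratio Delta = (max(y) - min(y)) / (max(x) - min(x)) of the projected
#' scatter plot. It drives the lattice shape so the lattice matches the
#' coordinate system of the projection. Degenerate extents (all points on a
#' vertical or horizontal line, or a single repeated point) fall back to
#' Delta = 1 so that collinear projections still yield a usable map.
#'
#' @param projection A data frame or matrix with n >= 2 rows; the first two
#'   columns are taken as the projected x and y coordinates.
#' @param eps Extents below `eps` are treated as degenerate.
#' @return A single positive number, the aspect ratio Delta.
#' @examples
#' compute_aspect_ratio(cbind(x = c(0, 10), y = c(0, 20)))  # 2
#' @export
compute_aspect_ratio <- function(projection, eps = 1e-12) {
  xy <- as_projection_matrix(projection)
  if (nrow(xy) < 2L) {
    stop("projection must contain at least 2 points", call. = FALSE)
  }
  dx <- max(xy[, 1]) - min(xy[, 1])
  dy <- max(xy[, 2]) - min(xy[, 2])
  if (!is.finite(dx) || !is.finite(dy)) {
    stop("projection coordinates must be finite", call. = FALSE)
  }
  if (dx < eps || dy < eps) return(1)
  dy / dx
}

#' Size the toroidal lattice from the projection shape and data size
#'
#' Solves the lattice-sizing conditions: (I) the lattice aspect ratio
#' (L - 1)/(C - 1) should approximate the projection's bounding-box ratio
#' Delta, and (II) the number of neurons L * C must be at least
#' `max(n_points, emergence_floor)` so that emergent structure can form on the
#' map. Condition (II) with (I) leads to the quadratic bound
#' L >= -(1 + Delta)/2 + sqrt(((1 + Delta)/2)^2 + NN * Delta), whose ceiling is
#' taken for L; C = round((L - 1)/Delta) + 1 and is then incremented until
#' L * C >= NN. Both dimensions are kept at 3 or more.
#'
#' @param delta Positive aspect ratio, from [compute_aspect_ratio()].
#' @param n_points Number of data points n.
#' @param emergence_floor Minimum neuron count for emergence; the map needs
#'   thousands of neurons (more than 4000) to act as a projection surface
#'   rather than a clustering, so the default floor is 4096 = 64^2.
#' @return An [esom_lattice()].
#' @examples
#' size_lattice(1, 150)     # 64 x 64: the emergence floor dominates
#' size_lattice(1, 4900, emergence_floor = 1)  # 70 x 70
#' @export
size_lattice <- function(delta, n_points, emergence_floor = 4096) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0,
            is.numeric(n_points), length(n_points) == 1L, n_points >= 1)
  nn <- max(n_points, emergence_floor)
  half <- (1 + delta) / 2
  bound <- -half + sqrt(half^2 + nn * delta)
  L <- max(3L, as.integer(ceiling(bound)))
  C <- max(3L, as.integer(round((L - 1) / delta)) + 1L)
  while (as.numeric(L) * C < nn) C <- C + 1L
  esom_lattice(L, C)
}

#' Eight toroidal Moore neighbours of a grid cell
#'
#' @param m Integer vector `c(line, column)`, 1-based.
#' @param lattice An [esom_lattice()].
#' @return An 8 x 2 integer matrix with columns `line`, `column`; one row per
#'   neighbour, wrapped around the torus.
#' @examples
#' toroidal_neighbors(c(1, 1), esom_lattice(4, 4))
#' @export
toroidal_neighbors <- function(m, lattice) {
  check_position(m, lattice)
  off <- cbind(line   = rep(-1:1, times = 3),
               column = rep(-1:1, each  = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  nb <- cbind(
    line   = wrap1(m[1] + off[, 1], lattice$L),
    column = wrap1(m[2] + off[, 2], lattice$C)
  )
  storage.mode(nb) <- "integer"
  unique(nb)
}

#' Toroidal grid distance between two cells
#'
#' Minimum-image Euclidean distance on the torus: each axis difference is
#' wrapped to `min(|delta|, extent - |delta|)` before the usual Euclidean
#' combination. This is the map-space distance `d(j, l)` used by the
#' neighbourhood function during training.
#'
#' @param a,b Integer vectors `c(line, column)`, 1-based.
#' @param lattice An [esom_lattice()].
#' @return A single non-negative number; zero iff `a == b`.
#' @examples
#' toroidal_grid_distance(c(1, 1), c(10, 10), esom_lattice(10, 10))  # sqrt(2)
#' @export
toroidal_grid_distance <- function(a, b, lattice) {
  check_position(a, lattice)
  check_position(b, lattice)
  dl <- abs(a[1] - b[1]); dl <- min(dl, lattice$L - dl)
  dc <- abs(a[2] - b[2]); dc <- min(dc, lattice$C - dc)
  sqrt(dl^2 + dc^2)
}

# wrap a 1-based coordinate onto [1, extent]
wrap1 <- function(i, extent) ((i - 1L) %% extent) + 1L

check_position <- function(m, lattice) {
  if (!inherits(lattice, "esom_lattice")) {
    stop("`lattice` must be an esom_lattice", call. = FALSE)
  }
  if (length(m) != 2L || any(is.na(m)) ||
      m[1] < 1 || m[1] > lattice$L || m[2] < 1 || m[2] > lattice$C) {
    stop("grid position out of lattice bounds", call. = FALSE)
  }
  invisible(TRUE)
}

# row-major cell index: (line, column) -> 1..L*C, line 1 first
cell_index <- function(line, column, lattice) {
  (as.integer(line) - 1L) * lattice$C + as.integer(column)
}

cell_position <- function(index, lattice) {
  index <- as.integer(index)
  cbind(line   = (index - 1L) %/% lattice$C + 1L,
        column = (index - 1L) %%  lattice$C + 1L)
}
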