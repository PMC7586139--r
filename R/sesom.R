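#' Training configuration for the simplified emergent SOM
#'
#' The training loop itself is parameter-free: the radius schedule is derived
#' from the lattice, and there is no learning rate or epoch count. What
#' remains configurable is the run seed (presentation-order shuffling and
#' prototype initialization) and the input-space metric.
#'
#' @param seed Integer seed; a fixed seed makes the run bit-reproducible.
#' @param metric Input-space distance, `"euclidean"` (default) or
#'   `"manhattan"`.
#' @return A list of class `sesom_config`.
#' @export
sesom_config <- function(seed = 1L, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  structure(list(seed = as.integer(seed), metric = metric),
            class = "sesom_config")
}

#' Radius cooling schedule
#'
#' Radii descend from `Rmax = C/6` (clamped below by 1) in steps of 1 down to
#' 1; when `Rmax` is not an integer the final step is fractional so the
#' schedule still ends exactly at 1. One radius step presents every data point
#' once.
#'
#' @param lattice An [esom_lattice()].
#' @return Numeric vector of radii, strictly descending, last element 1.
#' @examples
#' cooling_schedule(esom_lattice(64, 64))  # 10.67, 9.67, ..., 1.67, 1
#' @export
cooling_schedule <- function(lattice) {
  stopifnot(inherits(lattice, "esom_lattice"))
  rmax <- max(lattice$C / 6, 1)
  radii <- seq(rmax, 1, by = -1)
  if (radii[length(radii)] != 1) radii <- c(radii, 1)
  radii
}

#' Neighbourhood function of the simplified ESOM
#'
#' `h(d, R) = 1 - d^2 / (pi R^2)` when that ratio is below 1, and 0 otherwise.
#' It replaces both the learning rate and the classical Gaussian kernel: at
#' the best-matching unit (d = 0) the pull is total (h = 1), and influence
#' dies off linearly in squared map distance until the cutoff `d^2 = pi R^2`.
#'
#' @param d Non-negative map-space distance(s) (vectorised).
#' @param R Positive radius.
#' @return Value(s) in \[0, 1\].
#' @examples
#' neighborhood_h(0, 5)  # 1
#' neighborhood_h(1, 1)  # 1 - 1/pi
#' @export
neighborhood_h <- function(d, R) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0) {
    stop("`R` must be a single positive number", call. = FALSE)
  }
  ratio <- d^2 / (pi * R^2)
  ifelse(ratio < 1, 1 - ratio, 0)
}

#' Prototype grid constructor
#'
#' One d-dimensional prototype (weight vector) per lattice cell, stored as an
#' `(L*C) x d` matrix in row-major cell order (line 1 first).
#'
#' @param weights Numeric `(L*C) x d` matrix.
#' @param lattice An [esom_lattice()].
#' @return An object of class `esom_grid`.
#' @export
esom_grid <- function(weights, lattice) {
  stopifnot(inherits(lattice, "esom_lattice"))
  weights <- as.matrix(weights)
  if (nrow(weights) != lattice$L * lattice$C) {
    stop("weights must have one row per lattice cell", call. = FALSE)
  }
  if (!all(is.finite(weights))) {
    stop("all prototype entries must be finite", call. = FALSE)
  }
  structure(list(weights = weights, lattice = lattice, d = ncol(weights)),
            class = "esom_grid")
}

#' @export
print.esom_grid <- function(x, ...) {
  cat(sprintf("<esom_grid> %d x %d prototypes of dimension %d\n",
              x$lattice$L, x$lattice$C, x$d))
  invisible(x)
}

#' Best-matching unit of a data point
#'
#' The lattice cell whose prototype minimises the input-space distance to
#' `x`; ties are broken by the smallest (line, column) in lexicographic
#' order.
#'
#' @param x Numeric vector of length d.
#' @param grid An [esom_grid()].
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return Integer vector `c(line, column)`.
#' @export
find_bmu <- function(x, grid, metric = "euclidean") {
  stopifnot(inherits(grid, "esom_grid"))
  if (length(x) != grid$d) {
    stop("dimension of `x` does not match the prototype grid", call. = FALSE)
  }
  diffs <- sweep(grid$weights, 2, x)
  dist <- switch(match.arg(metric, c("euclidean", "manhattan")),
                 euclidean = rowSums(diffs^2),
                 manhattan = rowSums(abs(diffs)))
  k <- which.min(dist)  # first minimum = smallest row-major index
  as.integer(cell_position(k, grid$lattice))
}

#' Pull a neighbourhood of prototypes toward a data point
#'
#' Applies the sESOM update: every cell within the neighbourhood cutoff of
#' the best-matching unit moves toward `x` by the fraction
#' [neighborhood_h()] of the remaining difference,
#' `w <- w + h * (x - w)`. The BMU cell itself (h = 1) becomes exactly `x`;
#' cells at or beyond the cutoff are untouched.
#'
#' @param grid An [esom_grid()].
#' @param bmu Integer `c(line, column)` of the best-matching unit.
#' @param x Numeric vector of length d.
#' @param R Radius, >= 1.
#' @return The modified `esom_grid`.
#' @export
update_neighborhood <- function(grid, bmu, x, R) {
  stopifnot(inherits(grid, "esom_grid"), R >= 1)
  check_position(bmu, grid$lattice)
  lat <- grid$lattice
  pos <- cell_position(seq_len(lat$L * lat$C), lat)
  dl <- abs(pos[, 1] - bmu[1]); dl <- pmin(dl, lat$L - dl)
  dc <- abs(pos[, 2] - bmu[2]); dc <- pmin(dc, lat$C - dc)
  # squared grid distance fed to the kernel directly (no sqrt round-trip)
  ratio <- (dl^2 + dc^2) / (pi * R^2)
  h <- ifelse(ratio < 1, 1 - ratio, 0)
  act <- which(h > 0)
  grid$weights[act, ] <- grid$weights[act, , drop = FALSE] +
    h[act] * (matrix(x, length(act), grid$d, byrow = TRUE) -
                grid$weights[act, , drop = FALSE])
  grid
}

#' Train the simplified emergent SOM
#'
#' Prototypes at cells occupied by projected points ("predefined" cells) are
#' initialised to the mean of their assigned data points; all other
#' prototypes are initialised to data points sampled uniformly under the run
#' seed. For each radius of the [cooling_schedule()], every data point is
#' presented once in seeded-shuffled order: its current best-matching unit is
#' searched globally over all prototypes, and the neighbourhood around that
#' BMU is pulled toward the point. After each radius step the predefined
#' prototypes are reset to the (mean of the) data points assigned to them, so
#' on exit every occupied cell carries its data mean exactly.
#'
#' No learning rate, epoch count or radius needs to be supplied; the schedule
#' is fully derived from the lattice.
#'
#' @param data Numeric n x d matrix or data frame of the high-dimensional
#'   points.
#' @param assignment A `bmu_assignment` from [map_projection_to_grid()],
#'   consistent with `data` and `lattice`.
#' @param lattice The [esom_lattice()] the assignment was computed on.
#' @param config A [sesom_config()].
#' @return The trained [esom_grid()].
#' @export
train_sesom <- function(data, assignment, lattice = assignment$lattice,
                        config = sesom_config()) {
  X <- as_data_matrix(data)
  stopifnot(inherits(assignment, "bmu_assignment"),
            inherits(lattice, "esom_lattice"),
            inherits(config, "sesom_config"))
  n <- nrow(X)
  if (n < 1L) stop("data must contain at least one point", call. = FALSE)
  if (n != nrow(assignment$positions)) {
    stop("assignment does not match the number of data points", call. = FALSE)
  }
  if (lattice$L != assignment$lattice$L || lattice$C != assignment$lattice$C) {
    stop("assignment was computed on a different lattice", call. = FALSE)
  }

  nc <- lattice$L * lattice$C
  members <- cell_members(assignment)
  reset_means <- t(vapply(members$points,
                          function(idx) colMeans(X[idx, , drop = FALSE]),
                          numeric(ncol(X))))

  radii <- cooling_schedule(lattice)
  res <- withr::with_seed(config$seed, {
    init <- X[sample.int(n, nc, replace = TRUE), , drop = FALSE]
    init[members$cell, ] <- reset_means
    orders <- matrix(0L, n, length(radii))
    for (i in seq_along(radii)) orders[, i] <- sample.int(n) - 1L
    sesom_train_cpp(X, init, lattice$L, lattice$C, radii,
                    orders, members$cell - 1L, reset_means,
                    match(config$metric, c("euclidean", "manhattan")) - 1L)
  })
  esom_grid(res, lattice)
}

as_data_matrix <- function(data) {
  if (is.data.frame(data)) {
    data <- as.matrix(dplyr::select(data, dplyr::where(is.numeric)))
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric matrix or data frame", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("data must be finite", call. = FALSE)
  }
  data
}
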