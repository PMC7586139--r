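#' Benchmark dataset generators
#'
#' Deterministic (seeded) generators for the classic structure-discovery
#' benchmarks used throughout the package's tests and examples, each
#' returning a `labeled_dataset`: a list with `data` (numeric n x d matrix),
#' `labels` (integer vector, classes 1..k), `name` and `seed`.
#'
#' @name fixtures
NULL

new_labeled_dataset <- function(data, labels, name, seed) {
  structure(list(data = data, labels = as.integer(labels),
                 name = name, seed = as.integer(seed)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> '%s': %d points x %d dims, %d classes (seed %d)\n",
              x$name, nrow(x$data), ncol(x$data),
              length(unique(x$labels)), x$seed))
  invisible(x)
}

#' Two interlocked rings in 3-D (Chainlink)
#'
#' Two unit circles in orthogonal planes whose centres are offset by one
#' radius, so the rings interlock like chain links. The classes are not
#' linearly separable, and any linear 2-D projection must place some points
#' of different rings close together — the projection error that the
#' topographic map makes visible as a mountain ridge between nearby points.
#'
#' @param n Total number of points (even), half per ring.
#' @param noise_sd Standard deviation of isotropic Gaussian noise.
#' @param seed Seed.
#' @return A `labeled_dataset` with labels 1 (ring in the xy-plane) and
#'   2 (ring in the xz-plane).
#' @export
make_chainlink <- function(n = 500, noise_sd = 0.05, seed = 1) {
  stopifnot(n >= 20, n %% 2 == 0, noise_sd >= 0)
  withr::with_seed(seed, {
    half <- n %/% 2L
    t1 <- stats::runif(half, 0, 2 * pi)
    t2 <- stats::runif(half, 0, 2 * pi)
    ring1 <- cbind(cos(t1), sin(t1), 0)
    ring2 <- cbind(1 + cos(t2), 0, sin(t2))
    X <- rbind(ring1, ring2) +
      matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    colnames(X) <- c("x", "y", "z")
    new_labeled_dataset(X, rep(1:2, each = half), "chainlink", seed)
  })
}

#' Three clusters plus four outliers in 3-D
#'
#' Two elongated bars and one spherical blob, plus exactly four distant
#' outlier points carrying a fourth label. Structurally equivalent to the
#' classic bars-plus-outliers benchmark but regenerated here (hence the
#' "-like" name); the outliers are placed far enough out that their distance
#' to every cluster centre exceeds any within-cluster radius, so they appear
#' as volcanoes or isolated peaks on the map.
#'
#' @param n_per_cluster Points per cluster.
#' @param seed Seed.
#' @return A `labeled_dataset` with labels 1..3 (clusters) and 4 (outliers).
#' @export
make_lsun3d_like <- function(n_per_cluster = 100, seed = 1) {
  stopifnot(n_per_cluster >= 10)
  withr::with_seed(seed, {
    m <- n_per_cluster
    bar1 <- cbind(stats::runif(m, 0, 4), stats::rnorm(m, 0, 0.15),
                  stats::rnorm(m, 0, 0.15))
    bar2 <- cbind(stats::rnorm(m, 0, 0.15), stats::runif(m, 0, 4),
                  stats::rnorm(m, 0, 0.15))
    blob <- cbind(stats::rnorm(m, 6, 0.3), stats::rnorm(m, 6, 0.3),
                  stats::rnorm(m, 0, 0.3))
    outliers <- rbind(c(15, 15, 15), c(-12, 14, -10),
                      c(14, -12, 12), c(-10, -10, -14))
    X <- rbind(bar1, bar2, blob, outliers)
    colnames(X) <- c("x", "y", "z")
    new_labeled_dataset(X, c(rep(1:3, each = m), rep(4L, 4)),
                        "lsun3d_like", seed)
  })
}

#' Uniform points on the unit sphere (Golfball)
#'
#' Gaussian triples normalized to unit length: uniformly distributed points
#' on the sphere surface, a dataset with no distance-based cluster structure
#' at all. Its topographic map should show no clear valleys — the
#' absence-of-structure control.
#'
#' @param n Number of points, at least 50.
#' @param seed Seed.
#' @return A `labeled_dataset` with a single label.
#' @export
make_golfball <- function(n = 500, seed = 1) {
  stopifnot(n >= 50)
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(3 * n), n, 3)
    X <- X / sqrt(rowSums(X^2))
    colnames(X) <- c("x", "y", "z")
    new_labeled_dataset(X, rep(1L, n), "golfball", seed)
  })
}

#' Separable spherical Gaussian mixture
#'
#' `k` spherical Gaussian clusters of equal size with isotropic noise of
#' standard deviation `sd`, centres placed so that all pairwise centre
#' distances are at least `separation`. For `k <= d` the centres form a
#' regular simplex with all pairwise distances exactly equal to
#' `separation`, so the parameter genuinely controls the separation (a
#' testbed where one pair is much farther apart than another would let the
#' wide pair dominate the robust height normalization and mask the close
#' pair's ridge); for `k > d` random centres are drawn and rescaled so the
#' minimum pairwise distance equals `separation`.
#'
#' @param k Number of clusters.
#' @param n Total number of points (split as evenly as possible).
#' @param d Dimensionality.
#' @param separation Pairwise centre distance; 0 collapses all centres to
#'   the origin.
#' @param sd Within-cluster standard deviation per coordinate; the default
#'   0.05 with the default separation 5 gives well-separated compact
#'   clusters.
#' @param seed Seed.
#' @return A `labeled_dataset` with labels 1..k and an extra `centers`
#'   element (k x d matrix of the true cluster centres).
#' @export
make_gaussian_mixture <- function(k = 3, n = 300, d = 3, separation = 5,
                                  sd = 0.05, seed = 1) {
  stopifnot(k >= 1, n >= k, d >= 1, separation >= 0, sd >= 0)
  withr::with_seed(seed, {
    if (k == 1L || separation == 0) {
      centers <- matrix(0, k, d)
    } else if (k <= d) {
      # vertices of a regular simplex: scaled unit vectors, centred
      centers <- diag(separation / sqrt(2), k) |>
        (\(m) sweep(m, 2, colMeans(m)))()
      centers <- cbind(centers, matrix(0, k, d - k))
    } else {
      centers <- matrix(stats::rnorm(k * d), k, d)
      min_dist <- min(stats::dist(centers))
      while (min_dist < 1e-8) {  # essentially impossible, but guard anyway
        centers <- matrix(stats::rnorm(k * d), k, d)
        min_dist <- min(stats::dist(centers))
      }
      centers <- centers * (separation / min_dist)
    }
    sizes <- diff(round(seq(0, n, length.out = k + 1)))
    labels <- rep(seq_len(k), times = sizes)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = sd), n, d)
    colnames(X) <- paste0("x", seq_len(d))
    out <- new_labeled_dataset(X, labels, "gaussian_mixture", seed)
    out$centers <- centers
    out
  })
}

#' First-two-principal-components projection fixture
#'
#' A deterministic linear 2-D projection used as the reference input for the
#' pipeline: the scores of the centered data on its first two principal
#' axes, with the sign convention that each axis's largest-magnitude loading
#' is positive. The projection method itself is an input to the topographic
#' map, not part of it; this fixture just provides one that needs no
#' external tooling.
#'
#' @param data Numeric n x d matrix or data frame, d >= 2.
#' @return An n x 2 matrix with columns `pc1`, `pc2`.
#' @export
make_linear_projection <- function(data) {
  X <- as_data_matrix(data)
  if (ncol(X) < 2L) stop("data must have at least 2 columns", call. = FALSE)
  if (all(apply(X, 2, stats::sd) < 1e-12)) {
    stop("data is constant; no principal axes exist", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, `*`)
  colnames(scores) <- c("pc1", "pc2")
  scores
}

#' Write a labeled dataset and its projection fixture to CSV
#'
#' Writes `data.csv` (feature columns, with header), `proj.csv` (two
#' columns) and `labels.csv` (single column) into `dir`.
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if missing).
#' @param projection Optional n x 2 matrix; default is
#'   [make_linear_projection()] of the data.
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir, projection = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(projection)) projection <- make_linear_projection(dataset$data)
  readr::write_csv(tibble::as_tibble(dataset$data), file.path(dir, "data.csv"))
  readr::write_csv(tibble::as_tibble(as.data.frame(projection)),
                   file.path(dir, "proj.csv"))
  readr::write_csv(tibble::tibble(label = dataset$labels),
                   file.path(dir, "labels.csv"))
  invisible(dir)
}
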