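#' Robust normalization of U-heights
#'
#' Heights are rescaled by `(u - q01) / (q99 - q01)`, where `q01` and `q99`
#' are the 1st and 99th percentiles of all heights (linear interpolation
#' between order statistics), then clamped into \[0, 1\]. The percentile
#' anchoring makes the colour ramp robust against a few extreme peaks. When
#' all heights are (almost) equal, a zero map is returned.
#'
#' @param heights An `esom_umatrix` or a numeric matrix of heights.
#' @return Numeric matrix in \[0, 1\] with attributes `q01` and `q99`.
#' @export
robust_normalize <- function(heights) {
  H <- if (inherits(heights, "esom_umatrix")) heights$heights else heights
  H <- as.matrix(H)
  if (length(H) == 0L || !any(is.finite(H))) {
    stop("heights must contain at least one finite value", call. = FALSE)
  }
  q <- stats::quantile(H, c(0.01, 0.99), names = FALSE, type = 7)
  out <- if (q[2] > q[1]) {
    pmin(pmax((H - q[1]) / (q[2] - q[1]), 0), 1)
  } else {
    array(0, dim(H))
  }
  out <- matrix(out, nrow(H), ncol(H))
  attr(out, "q01") <- q[1]
  attr(out, "q99") <- q[2]
  out
}

#' Number of colour intervals from the height percentiles
#'
#' `ceil(q99 / q01)`, clamped into \[8, 64\]: a map whose heights span a wide
#' dynamic range gets more elevation classes. Degenerate percentiles (equal,
#' or `q01 = 0`) are absorbed by the clamps.
#'
#' @param q01,q99 First and 99th percentile of the raw U-heights.
#' @return A single integer in \[8, 64\].
#' @export
interval_count <- function(q01, q99) {
  stopifnot(q99 >= q01, q01 >= 0)
  ratio <- q99 / max(q01, .Machine$double.eps)
  as.integer(min(max(ceiling(ratio), 8), 64))
}

#' Hypsometric colour scale
#'
#' Elevation-coded colours in the cartographic convention: blue sea for small
#' distances, green and brown hills for middle distances, white peaks for
#' large distances. Colours for the requested number of elevation classes are
#' obtained by perceptually uniform interpolation of the key colours in
#' CIELab space. The key positions (sea below 0.15, shore, green hills,
#' brown, white from 0.8) are rendering constants of this package.
#'
#' @param keys Named numeric vector: positions in \[0, 1\] (names are hex
#'   colours). Must start at 0 and end at 1.
#' @return An object of class `hypsometric_scale`.
#' @export
hypsometric_scale <- function(keys = c(
  "#3C6BD8" = 0.00,  # deep sea blue
  "#55A8E2" = 0.10,  # shallow water
  "#8FD08F" = 0.15,  # shoreline green
  "#3E8E4C" = 0.30,  # hills
  "#C8BE64" = 0.50,  # dry grass
  "#8B5A2B" = 0.65,  # brown rock
  "#D8D0C8" = 0.80,  # scree
  "#FFFFFF" = 1.00   # snow
)) {
  stopifnot(is.numeric(keys), !is.null(names(keys)),
            keys[1] == 0, keys[length(keys)] == 1, !is.unsorted(keys))
  structure(list(colors = names(keys), positions = unname(keys)),
            class = "hypsometric_scale")
}

#' Interpolate a colour ramp in CIELab space
#'
#' @param scale A [hypsometric_scale()].
#' @param t Numeric vector of positions in \[0, 1\].
#' @return Character vector of hex colours.
#' @export
cielab_ramp <- function(scale, t) {
  stopifnot(inherits(scale, "hypsometric_scale"))
  srgb <- t(grDevices::col2rgb(scale$colors)) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  interp <- vapply(1:3, function(ch) {
    stats::approx(scale$positions, lab[, ch], xout = pmin(pmax(t, 0), 1),
                  rule = 2)$y
  }, numeric(length(t)))
  interp <- matrix(interp, ncol = 3)
  back <- grDevices::convertColor(interp, from = "Lab", to = "sRGB")
  back <- pmin(pmax(back, 0), 1)
  grDevices::rgb(back[, 1], back[, 2], back[, 3])
}

#' Bin normalized heights into elevation classes with hypsometric colours
#'
#' The \[0, 1\] range is split into `n_intervals` uniform intervals; each
#' interval is one elevation class, coloured by CIELab interpolation along
#' the hypsometric ramp at the interval midpoints. Class is a non-decreasing
#' function of height.
#'
#' @param normalized Numeric matrix in \[0, 1\] (from [robust_normalize()]).
#' @param scale A [hypsometric_scale()].
#' @param n_intervals Number of elevation classes (from [interval_count()]).
#' @return List with `class` (integer matrix, values in 1..n_intervals) and
#'   `colors` (hex colour per class).
#' @export
colorize <- function(normalized, scale = hypsometric_scale(),
                     n_intervals = 16) {
  M <- as.matrix(normalized)
  stopifnot(all(M >= 0 & M <= 1), n_intervals >= 1)
  cls <- pmin(floor(M * n_intervals) + 1L, n_intervals)
  cls <- matrix(as.integer(cls), nrow(M), ncol(M))
  mids <- (seq_len(n_intervals) - 0.5) / n_intervals
  list(class = cls, colors = cielab_ramp(scale, mids))
}

#' Outline maximal same-class regions as contour polylines
#'
#' Cells are grouped into maximal 8-connected regions of equal elevation
#' class (on the given non-wrapping view, e.g. the tiled display); the
#' boundary edges between different regions are traced into polylines in
#' grid coordinates (x = column, y = line; cell (l, c) occupies the unit
#' square centred on (c, l)). Interior boundaries close into loops;
#' boundaries that run into the array border remain open chains. The outer
#' border of the array itself is not outlined, so a uniform map has no
#' contours.
#'
#' @param class_matrix Integer matrix of elevation classes.
#' @return List of tibbles, each with columns `x`, `y` and an attribute
#'   `closed` (TRUE if the polyline is a loop).
#' @export
extract_contours <- function(class_matrix) {
  M <- as.matrix(class_matrix)
  L <- nrow(M); C <- ncol(M)
  lab <- label_components(M, toroidal = FALSE)

  # boundary segments between 4-adjacent cells of different regions,
  # as pairs of vertices on the half-integer corner grid (stored doubled
  # so keys stay integral)
  segs <- list()
  if (L > 1L) {
    diff_v <- lab[-L, , drop = FALSE] != lab[-1, , drop = FALSE]
    idx <- which(diff_v, arr.ind = TRUE)  # boundary below line idx[,1]
    if (nrow(idx)) {
      y <- 2L * idx[, 1] + 1L             # (line + 0.5) * 2
      segs[[length(segs) + 1L]] <- cbind(
        x1 = 2L * idx[, 2] - 1L, y1 = y,  # (col - 0.5, line + 0.5)
        x2 = 2L * idx[, 2] + 1L, y2 = y)  # (col + 0.5, line + 0.5)
    }
  }
  if (C > 1L) {
    diff_h <- lab[, -C, drop = FALSE] != lab[, -1, drop = FALSE]
    idx <- which(diff_h, arr.ind = TRUE)  # boundary right of column idx[,2]
    if (nrow(idx)) {
      x <- 2L * idx[, 2] + 1L
      segs[[length(segs) + 1L]] <- cbind(
        x1 = x, y1 = 2L * idx[, 1] - 1L,
        x2 = x, y2 = 2L * idx[, 1] + 1L)
    }
  }
  if (!length(segs)) return(list())
  segs <- do.call(rbind, segs)
  chain_segments(segs)
}

# chain undirected unit segments into polylines; coordinates are doubled
# integers, returned halved
chain_segments <- function(segs) {
  key <- function(x, y) paste(x, y, sep = "_")
  n_seg <- nrow(segs)
  v1 <- key(segs[, "x1"], segs[, "y1"])
  v2 <- key(segs[, "x2"], segs[, "y2"])
  incident <- split(rep(seq_len(n_seg), 2L), c(v1, v2))
  coords <- rbind(segs[, c("x1", "y1"), drop = FALSE],
                  segs[, c("x2", "y2"), drop = FALSE])
  rownames(coords) <- NULL
  vkey <- c(v1, v2)

  used <- logical(n_seg)
  out <- list()
  walk <- function(start_seg, start_vertex) {
    path <- start_vertex
    cur <- start_vertex
    seg <- start_seg
    repeat {
      used[seg] <<- TRUE
      ends <- c(v1[seg], v2[seg])
      cur <- ends[ends != cur][1]
      if (is.na(cur)) cur <- ends[1]  # degenerate zero-length guard
      path <- c(path, cur)
      nxt <- incident[[cur]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      seg <- nxt[1]
    }
    path
  }
  for (s in seq_len(n_seg)) {
    if (used[s]) next
    forward <- walk(s, v1[s])
    if (forward[length(forward)] == forward[1]) {
      path <- forward
    } else {
      # extend backwards from the start vertex if the chain is open there
      back_segs <- incident[[forward[1]]]
      back_segs <- back_segs[!used[back_segs]]
      path <- forward
      if (length(back_segs)) {
        backward <- walk(back_segs[1], forward[1])
        path <- c(rev(backward[-1]), forward)
      }
    }
    xy <- do.call(rbind, strsplit(path, "_", fixed = TRUE))
    poly <- tibble::tibble(x = as.numeric(xy[, 1]) / 2,
                           y = as.numeric(xy[, 2]) / 2)
    attr(poly, "closed") <- path[1] == path[length(path)]
    out[[length(out) + 1L]] <- poly
  }
  out
}

# 8-connected component labels of equal-valued cells; optionally toroidal
label_components <- function(M, toroidal = FALSE, mask = NULL) {
  L <- nrow(M); C <- ncol(M)
  id <- matrix(seq_len(L * C), L, C)
  if (is.null(mask)) mask <- matrix(TRUE, L, C)
  edges <- integer(0)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (off in offsets) {
    if (toroidal) {
      l2 <- (seq_len(L) - 1L + off[1]) %% L + 1L
      c2 <- (seq_len(C) - 1L + off[2]) %% C + 1L
      A <- id; B <- id[l2, c2, drop = FALSE]
      ok <- mask & mask[l2, c2, drop = FALSE] &
        (M == M[l2, c2, drop = FALSE])
    } else {
      lr <- seq_len(L); cr <- seq_len(C)
      l1 <- lr[lr + off[1] <= L & lr + off[1] >= 1L]
      c1 <- cr[cr + off[2] <= C & cr + off[2] >= 1L]
      if (!length(l1) || !length(c1)) next
      A <- id[l1, c1, drop = FALSE]
      B <- id[l1 + off[1], c1 + off[2], drop = FALSE]
      ok <- mask[l1, c1, drop = FALSE] &
        mask[l1 + off[1], c1 + off[2], drop = FALSE] &
        (M[l1, c1, drop = FALSE] == M[l1 + off[1], c1 + off[2], drop = FALSE])
    }
    edges <- c(edges, rbind(A[ok], B[ok]))
  }
  g <- igraph::make_graph(edges = edges, n = L * C, directed = FALSE)
  comp <- igraph::components(g)$membership
  comp[!mask] <- NA_integer_
  matrix(comp, L, C)
}

#' Tile the toroidal map two-by-two
#'
#' Because the lattice is a torus, the flat display shows every receptive
#' field four times: the map is replicated in a 2 x 2 block, giving a
#' 2L x 2C view in which every structure can be seen without seam cuts.
#'
#' @param M An L x C matrix (heights, classes, ...).
#' @return The 2L x 2C tiled matrix.
#' @export
tile_toroidal <- function(M) {
  M <- as.matrix(M)
  rbind(cbind(M, M), cbind(M, M))
}

#' Automatically cut an island out of the tiled display
#'
#' Chooses the cyclic shift of the toroidal map whose L x C window border
#' runs through the highest terrain, so the cut goes through mountains and
#' valleys stay intact. Every cell (hence every BMU) appears exactly once in
#' the window, whatever the shift. Ties are resolved by the lexicographically
#' smallest offset, so a flat map yields offset (0, 0).
#'
#' @param normalized Numeric L x C matrix of normalized heights.
#' @param bmus Optional `bmu_assignment`; returned re-indexed into the
#'   shifted window.
#' @return List with `offset` (`c(line, column)`, 0-based cyclic shift),
#'   `normalized` (the shifted L x C crop), `border_height` (objective value
#'   of the chosen offset) and, if given, `bmus` (tibble of shifted
#'   positions).
#' @export
cut_island <- function(normalized, bmus = NULL) {
  M <- as.matrix(normalized)
  L <- nrow(M); C <- ncol(M)
  rs <- rowSums(M); cs <- colSums(M)
  wrap <- function(i, n) (i - 1L) %% n + 1L

  # border objective for window starting at (1+dl, 1+dc):
  # top/bottom rows + left/right columns - doubly counted corners
  best <- -Inf; best_off <- c(0L, 0L)
  for (dl in 0:(L - 1L)) {
    r1 <- wrap(1L + dl, L); r2 <- wrap(L + dl, L)
    for (dc in 0:(C - 1L)) {
      c1 <- wrap(1L + dc, C); c2 <- wrap(C + dc, C)
      obj <- rs[r1] + rs[r2] + cs[c1] + cs[c2] -
        (M[r1, c1] + M[r1, c2] + M[r2, c1] + M[r2, c2])
      if (obj > best + 1e-12) {
        best <- obj
        best_off <- c(dl, dc)
      }
    }
  }
  dl <- best_off[1]; dc <- best_off[2]
  shifted <- M[wrap(seq_len(L) + dl, L), wrap(seq_len(C) + dc, C),
               drop = FALSE]
  out <- list(offset = c(line = dl, column = dc), normalized = shifted,
              border_height = best)
  if (!is.null(bmus)) {
    stopifnot(inherits(bmus, "bmu_assignment"))
    out$bmus <- bmus$positions |>
      dplyr::mutate(line   = wrap(.data$line - dl, L),
                    column = wrap(.data$column - dc, C))
  }
  out
}

#' Count valleys: the map's estimate of the number of clusters
#'
#' The toroidal map is thresholded at `sea_level`; 8-connected components of
#' low cells (normalized height strictly below the threshold) are the
#' candidate valleys. A valley is read as a cluster only if it actually
#' houses at least a `min_share` fraction of the projected points: robust
#' normalization stretches even a structure-free map across the full \[0, 1\]
#' range, so a noisy terrain always contains a few single-cell ponds holding
#' one or two points, and groups below a few percent of the data are outlier
#' groups (volcanoes), not clusters. Low regions with no points at all are
#' likewise ignored.
#'
#' @param normalized Numeric L x C matrix in \[0, 1\].
#' @param bmus A `bmu_assignment` for the same lattice.
#' @param sea_level Height threshold separating valleys from terrain;
#'   default 0.3 so that the blue elevation classes of the default ramp count
#'   as sea.
#' @param min_share Minimum fraction of the data points a low component must
#'   contain to count as a valley (default 0.05). At least one point is
#'   always required.
#' @return Integer count of valleys.
#' @export
count_valleys <- function(normalized, bmus, sea_level = 0.3,
                          min_share = 0.05) {
  M <- as.matrix(normalized)
  stopifnot(inherits(bmus, "bmu_assignment"),
            nrow(M) == bmus$lattice$L, ncol(M) == bmus$lattice$C,
            min_share >= 0, min_share < 1)
  low <- M < sea_level
  if (!any(low)) return(0L)
  lab <- label_components(matrix(1L, nrow(M), ncol(M)), toroidal = TRUE,
                          mask = low)
  bmu_cells <- cbind(bmus$positions$line, bmus$positions$column)
  bmu_labs <- lab[bmu_cells]
  bmu_labs <- bmu_labs[!is.na(bmu_labs)]
  if (!length(bmu_labs)) return(0L)
  need <- max(1, ceiling(min_share * nrow(bmus$positions)))
  sum(table(bmu_labs) >= need)
}
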