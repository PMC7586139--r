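#' Heights between adjacent best-matching-unit pairs
#'
#' The diagnostic behind reading projection errors off the map: pairs of
#' data points whose BMUs are toroidally adjacent on the lattice (grid
#' distance at most sqrt(2), i.e. same cell or Moore neighbours) are close
#' in the 2-D projection, but if they belong to different high-dimensional
#' structures the terrain between them is elevated. For each such pair the
#' mean normalized height of the two BMU cells is reported, together with
#' whether the pair crosses class labels. On a faithful map, cross-class
#' adjacent pairs sit on visibly higher ground than within-class pairs.
#'
#' @param map A `topographic_map` or `generalized_umatrix` (or a plain
#'   normalized L x C matrix, in which case `bmus` must be given).
#' @param labels Integer/factor vector, one label per data point.
#' @param bmus A `bmu_assignment`; defaults to the one stored in `map`.
#' @return A tibble with one row per adjacent pair: `point1`, `point2`,
#'   `cross` (TRUE if labels differ) and `height`.
#' @export
bmu_pair_heights <- function(map, labels, bmus = NULL) {
  if (inherits(map, "topographic_map")) {
    if (is.null(bmus)) bmus <- map$bmus
    M <- map$normalized
  } else {
    M <- as.matrix(map)
  }
  stopifnot(inherits(bmus, "bmu_assignment"),
            length(labels) == nrow(bmus$positions))
  lat <- bmus$lattice
  pos <- bmus$positions

  by_cell <- split(pos$point, pos$cell)
  occupied <- as.integer(names(by_cell))
  occ_pos <- cell_position(occupied, lat)

  # occupied cell -> its toroidal Moore neighbourhood (including itself)
  pair_rows <- purrr::map(seq_along(occupied), function(i) {
    nb <- toroidal_neighbors(occ_pos[i, ], lat)
    nb_cells <- c(occupied[i], cell_index(nb[, 1], nb[, 2], lat))
    nb_cells <- intersect(nb_cells, occupied)
    p1 <- by_cell[[as.character(occupied[i])]]
    purrr::map(nb_cells, function(cl) {
      p2 <- by_cell[[as.character(cl)]]
      pairs <- expand.grid(point1 = p1, point2 = p2)
      pairs <- pairs[pairs$point1 < pairs$point2, , drop = FALSE]
      if (!nrow(pairs)) return(NULL)
      h <- (M[cell_position(occupied[i], lat)] + M[cell_position(cl, lat)]) / 2
      tibble::tibble(point1 = pairs$point1, point2 = pairs$point2,
                     height = h)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(pair_rows))
  out <- dplyr::distinct(out, .data$point1, .data$point2,
                         .keep_all = TRUE)
  out$cross <- labels[out$point1] != labels[out$point2]
  out[, c("point1", "point2", "cross", "height")]
}
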