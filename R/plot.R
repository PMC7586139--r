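#' Plot a topographic map
#'
#' Draws the hypsometrically tinted map with black contours and the
#' projected points as markers at their best-matching units. By default the
#' full 2 x 2 tiled toroidal view is shown (every receptive field appears
#' four times); with `island = TRUE` the automatically cut L x C island is
#' drawn instead. Line 1 is the top row.
#'
#' @param object A `topographic_map` or `generalized_umatrix`.
#' @param island Draw the cut-out island instead of the tiled view.
#' @param show_bmus Draw the projected points.
#' @param contours Draw region contours (tiled view only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topographic_map <- function(object, island = FALSE,
                                     show_bmus = TRUE, contours = TRUE,
                                     ...) {
  x <- object
  if (island) {
    cls_m <- colorize(x$island$normalized,
                      n_intervals = x$n_intervals)$class
    cells <- grid_tibble(cls_m, "class")
    bmu_pos <- x$island$bmus
    conts <- list()
  } else {
    cells <- grid_tibble(x$tiled$class, "class")
    bmu_pos <- x$bmus$positions
    if (!is.null(bmu_pos)) {
      L <- x$lattice$L; C <- x$lattice$C
      bmu_pos <- dplyr::bind_rows(
        bmu_pos,
        dplyr::mutate(bmu_pos, line = .data$line + L),
        dplyr::mutate(bmu_pos, column = .data$column + C),
        dplyr::mutate(bmu_pos, line = .data$line + L,
                      column = .data$column + C)
      )
    }
    conts <- if (contours) x$contours else list()
  }
  cells$color <- x$colors[cells$class]

  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$column, y = .data$line)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$color)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()

  if (length(conts)) {
    cont_df <- dplyr::bind_rows(conts, .id = "contour_id")
    p <- p + ggplot2::geom_path(
      data = cont_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$contour_id),
      linewidth = 0.2, colour = "black")
  }

  if (show_bmus && !is.null(bmu_pos)) {
    if (!is.null(x$labels)) {
      reps <- nrow(bmu_pos) / length(x$labels)
      bmu_pos$label <- factor(rep(x$labels, reps))
      p <- p + ggplot2::geom_point(
        data = bmu_pos,
        ggplot2::aes(x = .data$column, y = .data$line,
                     colour = .data$label), size = 0.6) +
        ggplot2::labs(colour = "class")
    } else {
      p <- p + ggplot2::geom_point(
        data = bmu_pos,
        ggplot2::aes(x = .data$column, y = .data$line),
        size = 0.6, colour = "magenta")
    }
  }
  p
}

#' @rdname autoplot.topographic_map
#' @param x A `topographic_map`.
#' @param y Unused.
#' @export
plot.topographic_map <- function(x, y, ...) {
  print(autoplot.topographic_map(x, ...))
  invisible(x)
}

#' Render a topographic map to a PNG file
#'
#' Writes a raster image whose pixel dimensions are proportional to the map:
#' 2L x 2C for the tiled view, L x C for the island.
#'
#' @param map A `topographic_map` or `generalized_umatrix`.
#' @param path Output PNG path.
#' @param island Render the island instead of the tiled view.
#' @param pixels_per_cell Image resolution scale.
#' @param ... Passed on to [autoplot.topographic_map()].
#' @return The path, invisibly.
#' @export
render_topographic_map <- function(map, path, island = FALSE,
                                   pixels_per_cell = 6, ...) {
  stopifnot(inherits(map, "topographic_map"))
  mult <- if (island) 1L else 2L
  w <- mult * map$lattice$C * pixels_per_cell
  h <- mult * map$lattice$L * pixels_per_cell
  p <- autoplot.topographic_map(map, island = island, ...)
  grDevices::png(path, width = w, height = h)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
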