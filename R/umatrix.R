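#' Generalized U-matrix: U-heights over the trained prototype grid
#'
#' For every lattice cell, the U-height is the mean input-space distance
#' between the cell's prototype and the prototypes of its eight toroidal
#' Moore neighbours. High U-heights mark cluster borders (neighbouring
#' prototypes are far apart in input space); low U-heights mark cluster
#' interiors. Because the map is a torus, no border special-casing exists.
#'
#' @param grid A trained [esom_grid()].
#' @param metric Input-space distance, matching the training metric;
#'   `"euclidean"` (default) or `"manhattan"`.
#' @return An object of class `esom_umatrix`: list with `heights` (L x C
#'   matrix, line 1 in row 1), `lattice`, `metric`.
#' @export
compute_uheights <- function(grid, metric = c("euclidean", "manhattan")) {
  stopifnot(inherits(grid, "esom_grid"))
  metric <- match.arg(metric)
  lat <- grid$lattice
  if (lat$L < 3L || lat$C < 3L) {
    stop("lattice must be at least 3 x 3", call. = FALSE)
  }
  H <- uheights_cpp(grid$weights, lat$L, lat$C,
                    match(metric, c("euclidean", "manhattan")) - 1L)
  structure(list(heights = H, lattice = lat, metric = metric),
            class = "esom_umatrix")
}

#' @export
print.esom_umatrix <- function(x, ...) {
  cat(sprintf("<esom_umatrix> %d x %d U-heights in [%.4g, %.4g] (%s)\n",
              x$lattice$L, x$lattice$C, min(x$heights), max(x$heights),
              x$metric))
  invisible(x)
}

#' @rdname compute_uheights
#' @param x An `esom_umatrix`.
#' @param ... Unused.
#' @return For `tidy()`: a tibble with one row per cell (`line`, `column`,
#'   `height`).
#' @export
tidy.esom_umatrix <- function(x, ...) {
  grid_tibble(x$heights, value_name = "height")
}

#' Write U-heights as delimited text
#'
#' L rows by C columns, line 1 first, tab-separated, no header.
#'
#' @param umatrix An `esom_umatrix` (or a plain numeric matrix).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_uheights <- function(umatrix, path) {
  H <- if (inherits(umatrix, "esom_umatrix")) umatrix$heights else umatrix
  readr::write_tsv(as.data.frame(H), path, col_names = FALSE)
  invisible(path)
}

#' Read U-heights written by [write_uheights()]
#'
#' @param path File of L rows x C columns of numbers.
#' @return A numeric matrix.
#' @export
read_uheights <- function(path) {
  as.matrix(readr::read_tsv(path, col_names = FALSE,
                            show_col_types = FALSE, progress = FALSE))
}

# long tibble view of an L x C grid, row-major (line 1 first)
grid_tibble <- function(M, value_name = "value") {
  out <- tibble::tibble(
    line   = rep(seq_len(nrow(M)), each = ncol(M)),
    column = rep(seq_len(ncol(M)), times = nrow(M)),
    value  = as.vector(t(M))
  )
  names(out)[3] <- value_name
  out
}
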