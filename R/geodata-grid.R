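#' Plot extent in local metres
#'
#' Rectangular extent of a study plot in plot-local Cartesian coordinates
#' (metres, origin at a plot corner). The field design this package targets
#' uses 1,000 m2 plots of 20 x 50 m.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates in metres.
#' @return An object of class `plot_extent`.
#' @export
plot_extent <- function(x_min = 0, y_min = 0, x_max, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(y_min),
            is.numeric(x_max), is.numeric(y_max))
  if (!(x_max > x_min) || !(y_max > y_min)) {
    stop("degenerate extent: need x_max > x_min and y_max > y_min", call. = FALSE)
  }
  structure(list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                 x_max = as.numeric(x_max), y_max = as.numeric(y_max)),
            class = "plot_extent")
}

#' @export
print.plot_extent <- function(x, ...) {
  cat(sprintf("<plot_extent> [%g, %g] x [%g, %g] m (%g x %g m)\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              x$x_max - x$x_min, x$y_max - x$y_min))
  invisible(x)
}

extent_width  <- function(extent) extent$x_max - extent$x_min
extent_height <- function(extent) extent$y_max - extent$y_min

#' Regular analysis grid over a plot
#'
#' Cells are square with side `resolution`; cell centres sit at
#' `origin + (i - 0.5) * resolution`. Column index increases with x,
#' row index with y. The number of columns/rows is `ceiling(span / resolution)`
#' so the grid always covers the extent.
#'
#' @param extent A [plot_extent()].
#' @param resolution Cell side in metres (default 0.5, finer than the 2 x 5 m
#'   sampling lattice while keeping a 20 x 50 m plot at 4,000 cells).
#' @return An object of class `plot_grid`.
#' @export
plot_grid <- function(extent, resolution = 0.5) {
  stopifnot(inherits(extent, "plot_extent"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("resolution must be a single positive number (metres)", call. = FALSE)
  }
  n_cols <- as.integer(ceiling(extent_width(extent)  / resolution - 1e-9))
  n_rows <- as.integer(ceiling(extent_height(extent) / resolution - 1e-9))
  structure(list(extent = extent, resolution = as.numeric(resolution),
                 n_rows = n_rows, n_cols = n_cols),
            class = "plot_grid")
}

#' @export
print.plot_grid <- function(x, ...) {
  cat(sprintf("<plot_grid> %d rows x %d cols @ %g m\n",
              x$n_rows, x$n_cols, x$resolution))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [plot_grid()].
#' @return A two-column matrix (x, y), one row per cell in row-major order
#'   (row 1 = lowest y), matching the storage order of [raster_layer()] values.
#' @export
grid_centres <- function(grid) {
  stopifnot(inherits(grid, "plot_grid"))
  xs <- grid$extent$x_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution
  ys <- grid$extent$y_min + (seq_len(grid$n_rows) - 0.5) * grid$resolution
  cbind(x = rep(xs, times = grid$n_rows),
        y = rep(ys, each = grid$n_cols))
}

same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "plot_grid") && inherits(b, "plot_grid") &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$resolution - b$resolution) < tol &&
    abs(a$extent$x_min - b$extent$x_min) < tol &&
    abs(a$extent$y_min - b$extent$y_min) < tol
}

grid_fingerprint <- function(grid) {
  sprintf("%dx%d@%g+(%g,%g)", grid$n_rows, grid$n_cols, grid$resolution,
          grid$extent$x_min, grid$extent$y_min)
}

#' Single-band raster on a plot grid
#'
#' Values are stored as an `n_rows x n_cols` matrix; `values[r, c]` is the cell
#' whose centre is `(x_min + (c - 0.5) res, y_min + (r - 0.5) res)`. Missing
#' cells are `NA`.
#'
#' @param grid A [plot_grid()].
#' @param values Numeric vector (row-major, row 1 = lowest y) or matrix of
#'   dimension `n_rows x n_cols`.
#' @param units Free-text units tag (e.g. `"g N/kg"`, `"permil"`).
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, units = "") {
  stopifnot(inherits(grid, "plot_grid"))
  if (is.matrix(values)) {
    if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
      stop("values matrix must be n_rows x n_cols", call. = FALSE)
    }
    m <- values
  } else {
    if (length(values) != grid$n_rows * grid$n_cols) {
      stop("values length must equal n_rows * n_cols", call. = FALSE)
    }
    m <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  }
  storage.mode(m) <- if (is.logical(m)) "logical" else "double"
  structure(list(grid = grid, values = m, units = units),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> %d x %d @ %g m%s; %d missing",
              x$grid$n_rows, x$grid$n_cols, x$grid$resolution,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              sum(is.na(x$values))))
  if (length(v)) cat(sprintf("; range %.4g..%.4g", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Flatten a raster to a cell vector in grid_centres() order
#' @param raster A [raster_layer()].
#' @return Numeric vector, one value per cell (row-major, row 1 first).
#' @export
raster_values <- function(raster) {
  stopifnot(inherits(raster, "raster_layer"))
  as.vector(t(raster$values))
}
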