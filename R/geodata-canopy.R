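#' Rasterize canopy polygons onto a grid
#'
#' A cell belongs to the canopy iff its centre lies inside any polygon
#' (centre-containment, matching the "cell occupied" reading of canopy
#' membership). An empty canopy set yields an all-`FALSE` raster.
#'
#' @param canopies A [canopy_set()] in grid coordinates.
#' @param grid A [plot_grid()].
#' @return A logical [raster_layer()].
#' @export
rasterize_canopy <- function(canopies, grid) {
  stopifnot(inherits(canopies, "canopy_set"), inherits(grid, "plot_grid"))
  centres <- grid_centres(grid)
  inside <- rep(FALSE, nrow(centres))
  for (p in canopies$polygons) {
    inside <- inside | mgcv::in.out(rbind(p, p[1, , drop = FALSE]), centres)
  }
  r <- raster_layer(grid, as.numeric(inside), units = "canopy")
  r$values <- r$values > 0.5
  r
}

#' Distance to the nearest canopy cell
#'
#' For each grid cell, the Euclidean centre-to-centre distance (metres) to the
#' closest cell occupied by the invader; occupied cells get 0. With no occupied
#' cell at all (uninvaded plot) every cell is `NA` and a warning is raised.
#'
#' @param canopy_raster Logical [raster_layer()] from [rasterize_canopy()].
#' @return A numeric [raster_layer()] in metres.
#' @export
distance_to_canopy <- function(canopy_raster) {
  stopifnot(inherits(canopy_raster, "raster_layer"),
            is.logical(canopy_raster$values))
  grid <- canopy_raster$grid
  occ <- which(raster_values(canopy_raster))
  if (!length(occ)) {
    warning("no canopy cells: distance raster is all missing (uninvaded plot)",
            call. = FALSE)
    return(raster_layer(grid, rep(NA_real_, grid$n_rows * grid$n_cols), units = "m"))
  }
  centres <- grid_centres(grid)
  src <- centres[occ, , drop = FALSE]
  # blockwise nearest-source scan keeps memory at O(block * sources)
  n <- nrow(centres)
  d <- numeric(n)
  block <- max(1L, as.integer(2e6 / nrow(src)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dx <- outer(centres[idx, 1], src[, 1], "-")
    dy <- outer(centres[idx, 2], src[, 2], "-")
    d[idx] <- sqrt(do.call(pmin, as.data.frame(dx * dx + dy * dy)))
  }
  d[occ] <- 0
  raster_layer(grid, d, units = "m")
}
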