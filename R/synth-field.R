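#' Simulate a stationary Gaussian random field on a grid
#'
#' Mean-zero field whose covariance follows `C(h) = sill - gamma(h)` for the
#' given variogram model (total sill = nugget + partial sill; the nugget
#' appears as spatially uncorrelated variance). Simulation is by dense
#' Cholesky decomposition of the cell-centre covariance matrix with a 1e-10
#' diagonal jitter, which is adequate up to about 20,000 cells. The same seed
#' always returns the identical field.
#'
#' @param grid A [plot_grid()] with at most 20,000 cells.
#' @param model A [variogram_model()] with a finite sill (`nugget`,
#'   `exponential`, `spherical` or `gaussian`).
#' @param seed Integer seed (scoped: the global RNG stream is restored).
#' @return A [raster_layer()].
#' @export
gaussian_random_field <- function(grid, model, seed = 1L) {
  stopifnot(inherits(grid, "plot_grid"))
  n <- grid$n_rows * grid$n_cols
  if (n > 20000) {
    stop("grid too large for dense decomposition (", n, " > 20000 cells)",
         call. = FALSE)
  }
  centres <- grid_centres(grid)
  v <- simulate_field_at(centres, model, seed)
  raster_layer(grid, v)
}

# field values at arbitrary points; shared with the plot generator
simulate_field_at <- function(points, model, seed) {
  stopifnot(inherits(model, "variogram_model"))
  if (model$model %in% c("linear", "power")) {
    stop("model '", model$model,
         "' has no finite sill; cannot define the field covariance",
         call. = FALSE)
  }
  sill <- model$nugget + model$psill
  n <- nrow(points)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  if (sill <= 0) return(numeric(n))
  H <- as.matrix(stats::dist(points))
  C <- sill - model_semivariance(model, H)
  diag(C) <- sill + 1e-10
  L <- tryCatch(chol(C), error = function(e) {
    stop("covariance matrix for model '", model$model,
         "' is not positive definite even after jitter", call. = FALSE)
  })
  as.numeric(t(L) %*% stats::rnorm(n))
}
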