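#' Ordinary kriging of one tracer onto a grid
#'
#' Solves, per prediction cell, the ordinary-kriging system in semivariance
#' form: the pairwise sample semivariance matrix augmented with the
#' unbiasedness (sum-to-one) constraint via a Lagrange multiplier. The kriging
#' neighbourhood is all samples within `cutoff` of the target cell; if fewer
#' than `min_neighbours` fall inside, all samples are used (global kriging).
#' Cells receiving any negative weight (screening effect) are counted and
#' reported via the `n_negative_weight_cells` attribute, never clamped.
#'
#' @param x,y,z Sample coordinates (metres) and tracer values; coordinates
#'   must be unique.
#' @param model A [variogram_model()].
#' @param grid A [plot_grid()].
#' @param cutoff Neighbourhood radius in metres (default: full extent).
#' @param min_neighbours Below this count the neighbourhood falls back to all
#'   samples (default 8).
#' @param units Units tag for the prediction raster.
#' @return An object of class `isoscape`: list with `prediction` and
#'   `variance` [raster_layer()]s, the `model`, and the sample fingerprint.
#' @export
ordinary_krige <- function(x, y, z, model, grid, cutoff = Inf,
                           min_neighbours = 8, units = "") {
  stopifnot(inherits(model, "variogram_model"), inherits(grid, "plot_grid"))
  n <- length(x)
  if (n < 2) stop("need at least two samples for ordinary kriging", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) {
    stop("duplicate sample locations make the kriging system singular", call. = FALSE)
  }
  centres <- grid_centres(grid)
  ok <- krige_points(x, y, z, model, centres, cutoff, min_neighbours)
  iso <- structure(list(
    prediction = raster_layer(grid, ok$pred, units = units),
    variance   = raster_layer(grid, ok$var,  units = paste0("(", units, ")^2")),
    model      = model,
    sample_fingerprint = sample_fingerprint(x, y, z)
  ), class = "isoscape")
  attr(iso, "n_negative_weight_cells") <- ok$n_neg
  iso
}

#' @export
print.isoscape <- function(x, ...) {
  cat("<isoscape>", x$prediction$units, "model:", x$model$model, "\n")
  print(x$prediction)
  invisible(x)
}

sample_fingerprint <- function(x, y, z) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%.17g %.17g %.17g", x, y, z), f)
  unname(tools::md5sum(f))
}

# kriging at arbitrary points; shared by grid prediction and LOO-CV
krige_points <- function(x, y, z, model, targets, cutoff = Inf,
                         min_neighbours = 8) {
  n <- length(x)
  coords <- cbind(x, y)
  G <- model_semivariance(model, as.matrix(stats::dist(coords)))
  m <- nrow(targets)
  pred <- numeric(m); varr <- numeric(m); n_neg <- 0L

  solve_system <- function(idx, g0) {
    k <- length(idx)
    if (all(G[idx, idx] == 0) && all(g0 == 0)) {
      # an all-zero variogram (degenerate constant model): the limiting
      # ordinary-kriging solution is the equally-weighted mean
      return(c(rep(1 / k, k), 0))
    }
    A <- rbind(cbind(G[idx, idx, drop = FALSE], 1), c(rep(1, k), 0))
    b <- c(g0, 1)
    sol <- tryCatch(solve(A, b), error = function(e) {
      stop("singular kriging system (", length(idx), " neighbours, model ",
           model$model, ")", call. = FALSE)
    })
    sol
  }

  # distances target -> samples, blockwise
  block <- max(1L, as.integer(2e6 / n))
  for (start in seq(1L, m, by = block)) {
    rows <- start:min(start + block - 1L, m)
    dx <- outer(targets[rows, 1], x, "-")
    dy <- outer(targets[rows, 2], y, "-")
    D <- sqrt(dx * dx + dy * dy)
    for (j in seq_along(rows)) {
      d <- D[j, ]
      idx <- which(d <= cutoff)
      if (length(idx) < min_neighbours) idx <- seq_len(n)
      hit <- idx[d[idx] < 1e-12]
      g0 <- model_semivariance(model, d[idx])
      sol <- solve_system(idx, g0)
      lambda <- sol[seq_along(idx)]
      mu <- sol[length(sol)]
      if (any(lambda < -1e-10)) n_neg <- n_neg + 1L
      i <- rows[j]
      pred[i] <- sum(lambda * z[idx])
      varr[i] <- max(sum(lambda * g0) + mu, 0)
      if (length(hit) && model$nugget == 0) {
        # exact interpolation at a coincident sample location
        pred[i] <- z[hit[1]]; varr[i] <- 0
      }
    }
  }
  list(pred = pred, var = varr, n_neg = n_neg)
}

#' Kriging weights at a single target location
#'
#' Exposed mainly for verification: returns the ordinary-kriging weights and
#' Lagrange multiplier for one target.
#'
#' @inheritParams ordinary_krige
#' @param x0,y0 Target location (metres).
#' @return List with `weights`, `mu`, `prediction`, `variance`.
#' @export
kriging_weights <- function(x, y, z, model, x0, y0) {
  coords <- cbind(x, y)
  G <- model_semivariance(model, as.matrix(stats::dist(coords)))
  d0 <- sqrt((x - x0)^2 + (y - y0)^2)
  g0 <- model_semivariance(model, d0)
  k <- length(x)
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  sol <- solve(A, c(g0, 1))
  lambda <- unname(sol[1:k]); mu <- unname(sol[k + 1])
  list(weights = lambda, mu = mu,
       prediction = sum(lambda * z),
       variance = sum(lambda * g0) + mu)
}
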