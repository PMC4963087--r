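#' Default variogram cutoff for a plot
#'
#' One third of the longest diagonal of the plot extent — for a 20 x 50 m plot,
#' 17.95 m.
#'
#' @param extent A [plot_extent()].
#' @return Cutoff distance in metres.
#' @export
default_cutoff <- function(extent) {
  stopifnot(inherits(extent, "plot_extent"))
  sqrt(extent_width(extent)^2 + extent_height(extent)^2) / 3
}

#' Lag segmentation (variogram bin boundaries)
#'
#' @param boundaries Strictly increasing bin boundaries in metres. A leading 0
#'   is implied: bins are `(0, b1], (b1, b2], ...`.
#' @param label Optional display label.
#' @return An object of class `lag_segmentation`.
#' @export
lag_segmentation <- function(boundaries, label = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0) || boundaries[1] <= 0) {
    stop("boundaries must be >= 2 strictly increasing positive values", call. = FALSE)
  }
  structure(list(boundaries = boundaries,
                 label = if (is.null(label)) paste0("w", boundaries[1]) else label),
            class = "lag_segmentation")
}

#' Uniform lag segmentation of a given width
#' @param width Bin width in metres.
#' @param cutoff Maximum lag distance in metres.
#' @return A [lag_segmentation()].
#' @export
uniform_lags <- function(width, cutoff) {
  lag_segmentation(seq(width, cutoff + width * (1 - 1e-9), by = width),
                   label = sprintf("uniform %g m", width))
}

#' The candidate lag segmentations of the standard profile
#'
#' Five uniform widths (1, 1.2 default, 2, 3, 4 m) and one non-uniform
#' segmentation with boundaries 1, 2, 3, 4, 5, 6, 7, 9, 12, 15, 18 m.
#'
#' @param cutoff Cutoff distance in metres.
#' @return A named list of [lag_segmentation()] objects.
#' @export
standard_segmentations <- function(cutoff) {
  segs <- list(
    "uniform 1 m"   = uniform_lags(1,   cutoff),
    "uniform 1.2 m" = uniform_lags(1.2, cutoff),
    "uniform 2 m"   = uniform_lags(2,   cutoff),
    "uniform 3 m"   = uniform_lags(3,   cutoff),
    "uniform 4 m"   = uniform_lags(4,   cutoff),
    "non-uniform"   = lag_segmentation(c(1, 2, 3, 4, 5, 6, 7, 9, 12, 15, 18),
                                       label = "non-uniform")
  )
  segs
}

#' Empirical (method-of-moments) semivariogram
#'
#' gamma_hat_j = 1/(2 N_j) * sum over pairs in bin j of (z_i - z_k)^2, with
#' h_j the mean pair separation in the bin. Pairs separated by more than
#' `cutoff` are excluded; empty bins are dropped.
#'
#' @param x,y Sample coordinates (metres).
#' @param z Sample values.
#' @param seg A [lag_segmentation()].
#' @param cutoff Maximum pair separation (metres).
#' @return A data.frame of class `empirical_variogram` with columns
#'   `h` (mean lag), `gamma` (semivariance) and `np` (pair count).
#' @export
empirical_variogram <- function(x, y, z, seg, cutoff) {
  stopifnot(inherits(seg, "lag_segmentation"), length(x) == length(y),
            length(x) == length(z))
  n <- length(x)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  d <- stats::dist(cbind(x, y))
  sq <- stats::dist(cbind(z))^2
  keep <- d <= cutoff & d > 0
  if (!any(keep)) stop("no pairs within cutoff", call. = FALSE)
  d <- as.numeric(d)[keep]
  sq <- as.numeric(sq)[keep]
  bounds <- pmin(seg$boundaries, cutoff)
  bounds <- unique(bounds)
  bin <- findInterval(d, c(0, bounds), left.open = TRUE, rightmost.closed = FALSE)
  in_range <- bin >= 1 & bin <= length(bounds)
  bin <- bin[in_range]; d <- d[in_range]; sq <- sq[in_range]
  if (!length(bin)) stop("no pairs within cutoff", call. = FALSE)
  np <- tapply(sq, bin, length)
  g  <- tapply(sq, bin, sum) / (2 * np)
  h  <- tapply(d, bin, mean)
  out <- data.frame(h = as.numeric(h), gamma = as.numeric(g),
                    np = as.integer(np))
  out <- out[order(out$h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

# ---- parametric models -------------------------------------------------------

#' Supported variogram model names
#' @return Character vector.
#' @export
variogram_models <- function() {
  c("nugget", "exponential", "spherical", "gaussian", "linear", "power")
}

#' Parametric variogram model
#'
#' @param model One of [variogram_models()].
#' @param nugget Nugget c0 (>= 0); the discontinuity at the origin.
#' @param psill Partial sill c (>= 0). For `"linear"` this is the slope per
#'   metre; for `"power"` the coefficient of `h^p`.
#' @param range Range/scale parameter a (> 0; exponential and gaussian use it
#'   as the e-folding scale, spherical as the exact range). Ignored for
#'   `"nugget"`, `"linear"` and `"power"`.
#' @param p Exponent in (0, 2) for `"power"`.
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(model, nugget = 0, psill = 1, range = 1, p = 1) {
  model <- match.arg(model, variogram_models())
  if (nugget < 0 || psill < 0) stop("nugget and partial sill must be >= 0", call. = FALSE)
  if (model %in% c("exponential", "spherical", "gaussian") && range <= 0) {
    stop("range must be > 0", call. = FALSE)
  }
  if (model == "power" && (p <= 0 || p >= 2)) {
    stop("power exponent must lie in (0, 2)", call. = FALSE)
  }
  structure(list(model = model, nugget = as.numeric(nugget),
                 psill = as.numeric(psill), range = as.numeric(range),
                 p = as.numeric(p)),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget=%.4g psill=%.4g range=%.4g%s\n",
              x$model, x$nugget, x$psill, x$range,
              if (x$model == "power") sprintf(" p=%.3g", x$p) else ""))
  invisible(x)
}

#' Model semivariance gamma(h)
#'
#' Closed-form semivariance of the named model; gamma(0) = 0 by definition and
#' the nugget contributes for every h > 0.
#'
#' @param model A [variogram_model()].
#' @param h Lag distance(s), metres, >= 0.
#' @return Semivariance values, same length as `h`.
#' @export
model_semivariance <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("negative lag distance", call. = FALSE)
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  g <- switch(model$model,
    nugget      = rep(0, length(h)),
    exponential = c1 * (1 - exp(-h / a)),
    spherical   = ifelse(h < a, c1 * (1.5 * h / a - 0.5 * (h / a)^3), c1),
    gaussian    = c1 * (1 - exp(-(h / a)^2)),
    linear      = c1 * h,
    power       = c1 * h^model$p
  )
  out <- g + ifelse(h > 0, c0, 0)
  out[h == 0] <- 0
  out
}

n_free_params <- function(model_name) {
  switch(model_name,
    nugget = 1L,                      # c0
    linear = 2L, exponential = 3L,    # c0, c1 (, a)
    spherical = 3L, gaussian = 3L,
    power = 3L)                       # c0, c1, p
}

#' Fit a variogram model to an empirical variogram by weighted least squares
#'
#' Minimizes `sum_j w_j (gamma_hat_j - gamma(h_j))^2` with weights
#' `w_j = N_j / h_j^2` (the classical pair-count/lag-squared weighting).
#' Optimization uses box-constrained quasi-Newton from a moment-based start
#' plus `n_restarts` jittered restarts; the best objective wins.
#'
#' @param emp An [empirical_variogram()].
#' @param model_name One of [variogram_models()].
#' @param n_restarts Number of jittered restarts (default 5).
#' @param start Optional numeric start vector overriding the moment-based
#'   start (used to warm-start the leave-one-out refits).
#' @return A [variogram_model()] with attributes `wls` (objective value) and
#'   `converged`.
#' @export
fit_variogram <- function(emp, model_name, n_restarts = 5, start = NULL) {
  stopifnot(inherits(emp, "empirical_variogram"))
  model_name <- match.arg(model_name, variogram_models())
  npar <- n_free_params(model_name)
  if (nrow(emp) < npar) {
    stop(sprintf("too few variogram bins (%d) for a %d-parameter %s model",
                 nrow(emp), npar, model_name), call. = FALSE)
  }
  h <- emp$h; g <- emp$gamma; w <- emp$np / pmax(h, 1e-12)^2
  gmin <- min(g); gmax <- max(g); hmax <- max(h)
  scale_g <- max(gmax, 1e-12)

  # the numerical gradient of L-BFGS-B can probe just outside the box;
  # clamp before building the model so those probes stay feasible
  obj_for <- function(make_model, lower, upper) function(par) {
    m <- make_model(pmin(pmax(par, lower), upper))
    if (is.null(m)) return(1e30)
    sum(w * (g - model_semivariance(m, h))^2)
  }

  if (model_name == "nugget") {
    c0 <- sum(w * g) / sum(w)  # weighted mean, the exact WLS solution
    out <- variogram_model("nugget", nugget = c0, psill = 0)
    attr(out, "wls") <- sum(w * (g - c0)^2); attr(out, "converged") <- TRUE
    return(out)
  }

  make_model <- switch(model_name,
    linear = function(par) variogram_model("linear", par[1], par[2]),
    power  = function(par) {
      if (par[3] <= 1e-6 || par[3] >= 2 - 1e-6) return(NULL)
      variogram_model("power", par[1], par[2], p = par[3])
    },
    function(par) variogram_model(model_name, par[1], par[2], par[3])
  )
  if (is.null(start)) {
    start <- switch(model_name,
      linear = c(gmin, (gmax - gmin) / hmax),
      power  = c(gmin, (gmax - gmin) / hmax, 1),
      c(gmin, max(gmax - gmin, 1e-8 * scale_g), hmax / 2)
    )
  }
  lower <- switch(model_name,
    linear = c(0, 0),
    power  = c(0, 0, 1e-4),
    c(0, 0, 1e-3))
  upper <- switch(model_name,
    linear = c(2 * gmax, Inf),
    power  = c(2 * gmax, Inf, 2 - 1e-4),
    c(2 * gmax, 10 * gmax, 10 * hmax))
  start <- pmin(pmax(start, lower), upper)
  objective <- obj_for(make_model, lower, upper)

  best <- NULL
  set_jitter <- function(i) {
    if (i == 0) return(start)
    f <- stats::runif(length(start), 0.3, 1.8)
    pmin(pmax(start * f + 1e-6, lower), upper)
  }
  for (i in 0:n_restarts) {
    res <- tryCatch(
      stats::optim(set_jitter(i), objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    out <- make_model(start)
    attr(out, "wls") <- objective(start); attr(out, "converged") <- FALSE
    return(out)
  }
  out <- make_model(best$par)
  attr(out, "wls") <- best$value
  attr(out, "converged") <- TRUE
  out
}
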