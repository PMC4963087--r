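#' Invader-influence kernel
#'
#' Phenomenological response of a tracer to distance `d` (metres) from the
#' invader canopy.
#'
#' * `"exp_decay"`: `f(d) = A exp(-d / lambda_d)` — monotone enrichment
#'   strongest at the canopy (N concentration, delta-15N).
#' * `"hump"`: a difference of exponentials
#'   `f(d) = a exp(-d / lambda2) - b exp(-d / lambda_d)` with
#'   `lambda2 > lambda_d`, rescaled so the peak equals `amplitude` and
#'   `f(0) = -depression` (default 0) — the non-monotone, hump-shaped
#'   response motivated by a shift from facilitation near the invader to
#'   competition underneath it (delta-13C).
#'
#' With `depression = 0` the hump peaks at
#' `d* = lambda_d lambda2 / (lambda2 - lambda_d) * log(lambda2 / lambda_d)`.
#'
#' @param form `"exp_decay"` or `"hump"`.
#' @param amplitude Peak effect in tracer units.
#' @param lambda_d Primary decay length (m).
#' @param lambda2 Second (longer) decay length for `"hump"`.
#' @param depression For `"hump"`: size of the dip at `d = 0` relative to the
#'   background (tracer units, >= 0; default 0).
#' @return An object of class `influence_kernel`.
#' @export
influence_kernel <- function(form = c("exp_decay", "hump"), amplitude,
                             lambda_d, lambda2 = NULL, depression = 0) {
  form <- match.arg(form)
  stopifnot(is.numeric(amplitude), lambda_d > 0)
  coef <- NULL
  if (form == "hump") {
    if (is.null(lambda2) || lambda2 <= lambda_d) {
      stop("hump kernel needs lambda2 > lambda_d", call. = FALSE)
    }
    if (depression < 0) stop("depression must be >= 0", call. = FALSE)
    coef <- hump_coefficients(abs(amplitude), lambda_d, lambda2, depression)
    coef$sign <- sign(amplitude)
  }
  structure(list(form = form, amplitude = amplitude, lambda_d = lambda_d,
                 lambda2 = lambda2, depression = depression, coef = coef),
            class = "influence_kernel")
}

# solve f(d) = a e^{-d/l2} - b e^{-d/l1} for (a, b) such that
# max_d f = A and f(0) = a - b = -depression
hump_coefficients <- function(A, l1, l2, depression) {
  peak_of <- function(a, b) {
    dstar <- l1 * l2 / (l2 - l1) * log((b * l2) / (a * l1))
    dstar <- max(dstar, 0)
    list(d = dstar, value = a * exp(-dstar / l2) - b * exp(-dstar / l1))
  }
  gap <- function(a) peak_of(a, a + depression)$value - A
  lo <- A * 1e-3; hi <- A
  while (gap(hi) < 0) hi <- hi * 2
  a <- stats::uniroot(gap, c(lo, hi), tol = 1e-12)$root
  b <- a + depression
  list(a = a, b = b, d_peak = peak_of(a, b)$d)
}

#' Evaluate an influence kernel
#' @param kernel An [influence_kernel()].
#' @param d Distances (m), finite and >= 0.
#' @return Kernel values in tracer units.
#' @export
kernel_value <- function(kernel, d) {
  stopifnot(inherits(kernel, "influence_kernel"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  if (kernel$form == "exp_decay") {
    kernel$amplitude * exp(-d / kernel$lambda_d)
  } else {
    with(kernel$coef,
         sign * (a * exp(-d / kernel$lambda2) - b * exp(-d / kernel$lambda_d)))
  }
}

#' Influence raster from a distance-to-canopy raster
#'
#' @param distance A [raster_layer()] of canopy distances (m); all finite.
#' @param kernel An [influence_kernel()].
#' @return A [raster_layer()] of the per-cell kernel values.
#' @export
influence_field <- function(distance, kernel) {
  stopifnot(inherits(distance, "raster_layer"))
  v <- raster_values(distance)
  raster_layer(distance$grid, kernel_value(kernel, v), units = "effect")
}
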