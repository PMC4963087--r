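#' Fit the mixture family over parameterizations and component counts
#'
#' Runs [em_fit()] for every `(code, k)` cell with the deterministic Ward
#' initialization (the agglomeration is computed once and cut at each `k`).
#' Failed or non-converged fits leave their BIC cell missing.
#'
#' @param X Numeric matrix, `n x d`.
#' @param k_range Integer vector of component counts (default `1:20`).
#' @param codes Parameterization codes (default: all ten).
#' @param tol,max_iter,init_max_n,init_seed Passed to [em_fit()].
#' @param verbose Emit one progress line per code.
#' @return An object of class `bic_surface`: list with `bic` (matrix
#'   `length(k_range) x length(codes)`, dimnames k x code), `fits` (list of
#'   lists), `k_range`, `codes`, `n`, `d`.
#' @export
fit_family <- function(X, k_range = 1:20, codes = parameterizations(),
                       tol = 1e-8, max_iter = 1000,
                       init_max_n = 2000, init_seed = 1L, verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (!length(k_range)) stop("k_range must be nonempty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  vapply(codes, check_code, character(1))

  # one agglomeration serves every (code, k)
  idx <- seq_len(n)
  if (n > init_max_n) idx <- local_seed_sample(n, init_max_n, init_seed)
  hc <- ward_tree(X[idx, , drop = FALSE])
  z_for_k <- function(k) {
    if (k == 1) return(matrix(1, n, 1))
    lab_sub <- stats::cutree(hc, k = k)
    centroids <- vapply(seq_len(k), function(j)
      colMeans(X[idx[lab_sub == j], , drop = FALSE]), numeric(d))
    centroids <- matrix(centroids, nrow = d)
    d2 <- vapply(seq_len(k), function(j)
      rowSums(sweep(X, 2, centroids[, j])^2), numeric(n))
    lab <- max.col(-matrix(d2, nrow = n), ties.method = "first")
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), lab)] <- 1
    z
  }
  z_cache <- lapply(k_range, z_for_k)

  B <- matrix(NA_real_, length(k_range), length(codes),
              dimnames = list(k = k_range, code = codes))
  fits <- stats::setNames(vector("list", length(codes)), codes)
  for (ci in seq_along(codes)) {
    fits[[ci]] <- stats::setNames(vector("list", length(k_range)),
                                  as.character(k_range))
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      if (n <= k) next
      fit <- tryCatch(
        suppressWarnings(
          em_fit(X, k, codes[ci], z0 = z_cache[[ki]], tol = tol,
                 max_iter = max_iter)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        fits[[ci]][[ki]] <- fit
        # degenerate fits (a component collapsed onto the covariance floor)
        # carry meaningless likelihood spikes; their BIC cell stays missing
        if (!isTRUE(fit$degenerate)) B[ki, ci] <- bic(fit)
      }
    }
    if (verbose) {
      message(sprintf("  %s: best BIC %.2f", codes[ci],
                      suppressWarnings(max(B[, ci], na.rm = TRUE))))
    }
  }
  if (all(is.na(B))) stop("every (code, k) fit failed", call. = FALSE)
  structure(list(bic = B, fits = fits, k_range = k_range, codes = codes,
                 n = n, d = d),
            class = "bic_surface")
}

#' @export
print.bic_surface <- function(x, ...) {
  best <- best_fit(x)
  cat(sprintf("<bic_surface> %d x %d cells (%d finite); best: %s, k=%d, BIC=%.2f\n",
              nrow(x$bic), ncol(x$bic), sum(is.finite(x$bic)),
              best$code, best$k, x$bic[as.character(best$k), best$code]))
  invisible(x)
}

#' Best (code, k) cell of a BIC surface
#' @param surface A [fit_family()] result.
#' @return List with `code`, `k` and the `mixture_fit`.
#' @export
best_fit <- function(surface) {
  stopifnot(inherits(surface, "bic_surface"))
  w <- which(surface$bic == max(surface$bic, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(code = surface$codes[w[2]], k = surface$k_range[w[1]],
       fit = surface$fits[[w[2]]][[w[1]]])
}

#' Select the mixture model at the beginning of the BIC plateau
#'
#' The parameterization is that of the global BIC maximum. Along that code's
#' BIC curve, with gains `g(k) = BIC(k) - BIC(k_prev)`, the chosen `k` is the
#' smallest one whose *next* gain is at most `tau * (max BIC - BIC(k_min))` —
#' i.e. the lowest number of components at which the curve has levelled off.
#' If no `k` qualifies (the curve still rises steeply at `k_max`), the BIC
#' argmax is returned with a warning.
#'
#' @param surface A [fit_family()] result.
#' @param tau Plateau threshold as a fraction of the curve's total rise
#'   (default 0.01).
#' @return List with `code`, `k`, `fit`, `tau`, `plateau` (logical: plateau
#'   rule applied, or fallback) and `curve` (the BIC values used).
#' @export
select_model_plateau <- function(surface, tau = 0.01) {
  stopifnot(inherits(surface, "bic_surface"))
  if (!any(is.finite(surface$bic))) stop("empty BIC surface", call. = FALSE)
  code <- best_fit(surface)$code
  curve <- surface$bic[, code]
  ks <- surface$k_range[is.finite(curve)]
  vals <- curve[is.finite(curve)]
  if (length(vals) == 1) {
    # a single admissible model size (e.g. fully degenerate data where every
    # k > 1 fit collapses): nothing to compare, take it as-is
    ki <- match(ks, surface$k_range)
    ci <- match(code, surface$codes)
    return(list(code = code, k = ks, fit = surface$fits[[ci]][[ki]],
                tau = tau, plateau = FALSE,
                curve = stats::setNames(vals, ks)))
  }
  scale <- max(vals) - vals[1]
  gains <- diff(vals)
  thresh <- tau * scale
  k_star <- NA_integer_
  for (i in seq_along(gains)) {
    if (gains[i] <= thresh) { k_star <- ks[i]; break }
  }
  plateau <- !is.na(k_star)
  if (!plateau) {
    k_star <- ks[which.max(vals)]
    warning("BIC curve has no plateau within k_range; using the BIC argmax k = ",
            k_star, call. = FALSE)
  }
  ki <- match(k_star, surface$k_range)
  ci <- match(code, surface$codes)
  list(code = code, k = k_star, fit = surface$fits[[ci]][[ki]],
       tau = tau, plateau = plateau,
       curve = stats::setNames(vals, ks))
}

#' Export a BIC surface as CSV (rows k, columns code)
#' @param surface A [fit_family()] result.
#' @param path Output path.
#' @export
write_bic_surface <- function(surface, path) {
  df <- data.frame(k = surface$k_range, surface$bic, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
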