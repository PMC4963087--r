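#' Leave-one-out cross-validation of one (model, segmentation) candidate
#'
#' Each sample is left out in turn; the empirical variogram is re-estimated and
#' re-fitted from the remaining samples and the left-out location is kriged
#' from them. Returns the LOO predictions, `RMSE = sqrt(mean((zhat - z)^2))`
#' and the R-squared of the ordinary least-squares regression (with intercept)
#' of predicted on measured values. R-squared is `NA` when the predictions are
#' constant (e.g. a degenerate constant field).
#'
#' @param x,y,z Sample coordinates and values.
#' @param model_name One of [variogram_models()].
#' @param seg A [lag_segmentation()].
#' @param cutoff Cutoff distance (metres), used both for variogram pairs and
#'   as the kriging neighbourhood radius.
#' @param n_restarts Restarts passed to [fit_variogram()].
#' @return An object of class `cv_result`: list with `predicted`, `rmse`,
#'   `r_squared`, `converged`, `model_name`, `seg_label`.
#' @export
loo_cross_validate <- function(x, y, z, model_name, seg, cutoff,
                               n_restarts = 5) {
  n <- length(z)
  if (n < 4) stop("need at least four samples for LOO-CV", call. = FALSE)
  pred <- rep(NA_real_, n)
  converged <- TRUE
  # multi-start fit on the full data; each leave-one-out refit is then
  # warm-started from these parameters (a single quasi-Newton descent)
  full_fit <- tryCatch({
    emp_full <- empirical_variogram(x, y, z, seg, cutoff)
    fit_variogram(emp_full, model_name, n_restarts = n_restarts)
  }, error = function(e) NULL)
  warm <- if (!is.null(full_fit) && isTRUE(attr(full_fit, "converged"))) {
    switch(model_name,
           nugget = NULL,
           linear = c(full_fit$nugget, full_fit$psill),
           power  = c(full_fit$nugget, full_fit$psill, full_fit$p),
           c(full_fit$nugget, full_fit$psill, full_fit$range))
  } else NULL
  for (i in seq_len(n)) {
    xi <- x[-i]; yi <- y[-i]; zi <- z[-i]
    fit <- tryCatch({
      emp <- empirical_variogram(xi, yi, zi, seg, cutoff)
      if (is.null(warm)) {
        fit_variogram(emp, model_name, n_restarts = n_restarts)
      } else {
        fit_variogram(emp, model_name, n_restarts = 0, start = warm)
      }
    }, error = function(e) NULL)
    if (is.null(fit) || !isTRUE(attr(fit, "converged"))) {
      converged <- FALSE
      break
    }
    ok <- tryCatch(
      krige_points(xi, yi, zi, fit, cbind(x[i], y[i]), cutoff = cutoff),
      error = function(e) NULL)
    if (is.null(ok)) { converged <- FALSE; break }
    pred[i] <- ok$pred
  }
  rmse <- if (converged) sqrt(mean((pred - z)^2)) else NA_real_
  r2 <- NA_real_
  if (converged && stats::sd(pred) > 1e-12 && stats::sd(z) > 1e-12) {
    r2 <- summary(stats::lm(pred ~ z))$r.squared
  }
  structure(list(predicted = pred, rmse = rmse, r_squared = r2,
                 converged = converged, model_name = model_name,
                 seg_label = seg$label),
            class = "cv_result")
}

#' Select the interpolation model by cross-validated RMSE
#'
#' Runs [loo_cross_validate()] for every `(model, segmentation)` candidate and
#' returns the convergent candidate with the smallest RMSE. Ties (within 1e-9
#' relative) are broken by higher R-squared, then by fewer model parameters,
#' then by candidate order. The full ranking is kept in `$report`.
#'
#' @param x,y,z Sample coordinates and values.
#' @param models Character vector of model names (default: all supported).
#' @param segmentations List of [lag_segmentation()]s (default: the standard
#'   six for the given cutoff).
#' @param cutoff Cutoff distance (metres).
#' @param n_restarts Restarts per variogram fit.
#' @param verbose Emit a progress line per candidate.
#' @return List with `model` (a fitted [variogram_model()] on the full data),
#'   `segmentation`, `cv` (the winning `cv_result`) and `report` (data.frame,
#'   one row per candidate).
#' @export
select_interpolation_model <- function(x, y, z,
                                       models = variogram_models(),
                                       segmentations = NULL,
                                       cutoff, n_restarts = 5,
                                       verbose = FALSE) {
  if (is.null(segmentations)) segmentations <- standard_segmentations(cutoff)
  cand <- expand.grid(model = models,
                      seg = seq_along(segmentations),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cand))
  cvs <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    mn <- cand$model[i]; seg <- segmentations[[cand$seg[i]]]
    cv <- tryCatch(
      loo_cross_validate(x, y, z, mn, seg, cutoff, n_restarts = n_restarts),
      error = function(e) NULL)
    if (is.null(cv)) {
      cv <- structure(list(predicted = NULL, rmse = NA_real_,
                           r_squared = NA_real_, converged = FALSE,
                           model_name = mn, seg_label = seg$label),
                      class = "cv_result")
    }
    cvs[[i]] <- cv
    rows[[i]] <- data.frame(model = mn, segmentation = seg$label,
                            rmse = cv$rmse, r_squared = cv$r_squared,
                            n_params = n_free_params(mn),
                            converged = cv$converged)
    if (verbose) {
      message(sprintf("  CV %-11s %-13s rmse=%s", mn, seg$label,
                      if (is.na(cv$rmse)) "failed" else sprintf("%.4g", cv$rmse)))
    }
  }
  report <- do.call(rbind, rows)
  ok <- which(report$converged & is.finite(report$rmse))
  if (!length(ok)) stop("no convergent interpolation candidate", call. = FALSE)
  best_rmse <- min(report$rmse[ok])
  tied <- ok[report$rmse[ok] <= best_rmse * (1 + 1e-9) + 1e-300]
  r2 <- report$r_squared[tied]
  r2[is.na(r2)] <- -Inf
  tied <- tied[order(-r2, report$n_params[tied], tied)]
  win <- tied[1]
  report$chosen <- seq_len(nrow(report)) == win
  seg <- segmentations[[cand$seg[win]]]
  emp <- empirical_variogram(x, y, z, seg, cutoff)
  final <- fit_variogram(emp, cand$model[win], n_restarts = n_restarts)
  list(model = final, segmentation = seg, cv = cvs[[win]], report = report)
}
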