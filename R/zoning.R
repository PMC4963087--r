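#' Stack three tracer isoscapes into a clustering matrix
#'
#' Aligns the N concentration, delta-15N and delta-13C isoscapes (which must
#' share one grid) and builds the `n_cells x 3` matrix fed to the mixture
#' model. Cells missing any layer are excluded and tracked.
#'
#' @param iso_n,iso_15N,iso_13C [ordinary_krige()] results (or bare
#'   [raster_layer()]s) for N concentration, delta-15N and delta-13C.
#' @return An object of class `isoscape_stack`: list with `X` (matrix with
#'   columns `n_conc, d15N, d13C`), `cell_index` (row -> cell), `grid`,
#'   `units`, `n_excluded`.
#' @export
stack_isoscapes <- function(iso_n, iso_15N, iso_13C) {
  layer <- function(x) if (inherits(x, "isoscape")) x$prediction else x
  layers <- list(n_conc = layer(iso_n), d15N = layer(iso_15N),
                 d13C = layer(iso_13C))
  stopifnot(all(vapply(layers, inherits, logical(1), "raster_layer")))
  g <- layers[[1]]$grid
  for (nm in names(layers)[-1]) {
    if (!same_grid(g, layers[[nm]]$grid)) {
      stop("isoscape grids differ (", grid_fingerprint(g), " vs ",
           grid_fingerprint(layers[[nm]]$grid), ")", call. = FALSE)
    }
  }
  M <- cbind(n_conc = raster_values(layers$n_conc),
             d15N = raster_values(layers$d15N),
             d13C = raster_values(layers$d13C))
  keep <- stats::complete.cases(M)
  structure(list(X = M[keep, , drop = FALSE],
                 cell_index = which(keep),
                 grid = g,
                 units = vapply(layers, function(l) l$units, character(1)),
                 n_excluded = sum(!keep)),
            class = "isoscape_stack")
}

#' @export
print.isoscape_stack <- function(x, ...) {
  cat(sprintf("<isoscape_stack> %d cells x 3 tracers (%d excluded) on %s\n",
              nrow(x$X), x$n_excluded, grid_fingerprint(x$grid)))
  invisible(x)
}

#' Partition a plot into homogeneous zones
#'
#' Clusters the raw (unstandardized) three-tracer cell matrix with the
#' constrained Gaussian mixture family, selects the model at the beginning of
#' the BIC plateau, assigns each cell its MAP component, and relabels zones
#' 1..k by ascending median N concentration (so zone 1 is always the
#' low-nitrogen background).
#'
#' @param stack An [stack_isoscapes()] result.
#' @param k_range,codes,tau,tol,max_iter Mixture settings
#'   (see [fit_family()] and [select_model_plateau()]).
#' @param standardize Standardize columns before clustering (default `FALSE`:
#'   the tracers enter on their native scales).
#' @param verbose Passed to [fit_family()].
#' @return An object of class `zone_map`: list with `labels`
#'   (integer [raster_layer()], 0 = excluded cell), `k`, `code`, `tau`,
#'   `fit`, `surface`, `zone_sizes`, `cell_labels`.
#' @export
cluster_plot <- function(stack, k_range = 1:20, codes = parameterizations(),
                         tau = 0.01, tol = 1e-8, max_iter = 1000,
                         standardize = FALSE, verbose = FALSE) {
  stopifnot(inherits(stack, "isoscape_stack"))
  if (nrow(stack$X) < 10) stop("need at least 10 cells to cluster", call. = FALSE)
  X <- stack$X
  if (standardize) X <- scale(X)
  surface <- fit_family(X, k_range = k_range, codes = codes, tol = tol,
                        max_iter = max_iter, verbose = verbose)
  sel <- select_model_plateau(surface, tau = tau)
  lab <- classify(sel$fit)
  # relabel by ascending median N concentration
  med_n <- tapply(stack$X[, "n_conc"], lab, stats::median)
  ord <- order(med_n)                 # ord[new] = old
  remap <- match(seq_along(ord), ord) # remap[old] = new
  lab <- remap[lab]
  full <- integer(stack$grid$n_rows * stack$grid$n_cols)
  full[stack$cell_index] <- lab
  structure(list(labels = raster_layer(stack$grid, as.numeric(full),
                                       units = "zone"),
                 k = sel$k, code = sel$code, tau = tau,
                 fit = sel$fit, surface = surface,
                 zone_sizes = as.integer(table(factor(lab, levels = seq_len(sel$k)))),
                 cell_labels = lab),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d zones (%s, tau=%g); sizes: %s\n",
              x$k, x$code, x$tau, paste(x$zone_sizes, collapse = ", ")))
  invisible(x)
}

#' Per-zone medians and post-hoc letters
#'
#' Summarizes each zone by its median N concentration, delta-15N, delta-13C
#' and (when a distance raster is supplied, i.e. for invaded plots) the median
#' distance to the nearest invader canopy, together with Kruskal-Wallis
#' statistics and compact letter displays per variable.
#'
#' @param zonemap A [cluster_plot()] result.
#' @param stack The [stack_isoscapes()] it was built from.
#' @param distance Optional distance [raster_layer()] from
#'   [distance_to_canopy()]; `NULL` for uninvaded plots.
#' @param alpha Significance level for the post-hoc letters (default 0.05).
#' @return An object of class `zone_summary`: list with `table` (data.frame,
#'   one row per zone) and `tests` (per-variable Kruskal-Wallis + letters).
#' @export
zone_summaries <- function(zonemap, stack, distance = NULL, alpha = 0.05) {
  stopifnot(inherits(zonemap, "zone_map"), inherits(stack, "isoscape_stack"))
  lab <- zonemap$cell_labels
  X <- stack$X
  k <- zonemap$k
  zf <- factor(lab, levels = seq_len(k))
  med <- function(v) as.numeric(tapply(v, zf, stats::median))
  tab <- data.frame(zone = seq_len(k),
                    n_cells = as.integer(table(zf)),
                    median_n_conc = med(X[, "n_conc"]),
                    median_d15N = med(X[, "d15N"]),
                    median_d13C = med(X[, "d13C"]))
  dvals <- NULL
  if (!is.null(distance)) {
    stopifnot(inherits(distance, "raster_layer"))
    dvals <- raster_values(distance)[stack$cell_index]
    tab$median_dist <- if (all(is.na(dvals))) NA_real_ else
      as.numeric(tapply(dvals, zf, stats::median, na.rm = TRUE))
  } else {
    tab$median_dist <- NA_real_
  }
  tests <- list()
  vars <- list(n_conc = X[, "n_conc"], d15N = X[, "d15N"], d13C = X[, "d13C"])
  if (!is.null(dvals) && !all(is.na(dvals))) vars$dist <- dvals
  for (nm in names(vars)) {
    if (k >= 2) {
      kw <- kruskal_wallis(vars[[nm]], lab)
      ph <- posthoc_mean_ranks(vars[[nm]], lab, alpha = alpha)
      tests[[nm]] <- list(kw = kw, posthoc = ph)
      tab[[paste0("letters_", nm)]] <- ph$letters
    } else {
      tests[[nm]] <- NULL
      tab[[paste0("letters_", nm)]] <- "a"
    }
  }
  structure(list(table = tab, tests = tests, alpha = alpha),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Kruskal-Wallis rank sum test
#'
#' H with the midrank tie correction, `df = k - 1`, and the p-value from the
#' chi-square approximation. With all values identical the statistic is
#' defined as 0 with p = 1 (and a warning), rather than the 0/0 of the tie
#' correction.
#'
#' @param values Numeric vector.
#' @param labels Group labels, same length.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    warning("all values identical; H = 0 by convention", call. = FALSE)
    return(list(H = 0, df = nlevels(labels) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Post-hoc multiple comparison of mean ranks after Kruskal-Wallis
#'
#' For each zone pair `(i, j)` the mean-rank difference is declared
#' significant iff
#' `|Rbar_i - Rbar_j| > z(1 - alpha / (k (k - 1))) * sqrt(n (n + 1) / 12 * (1/n_i + 1/n_j))`
#' (the classical alpha-inflation-corrected criterion). Compact letters are
#' assigned by greedy first-fit insertion over zones sorted by mean rank, so
#' that zones sharing a letter are not significantly different.
#'
#' @param values Numeric vector.
#' @param labels Group labels.
#' @param alpha Familywise significance level (default 0.05).
#' @return List with `comparisons` (data.frame: pair, observed and critical
#'   difference, significance), `letters` (one string per group, in group
#'   level order) and `alpha`.
#' @export
posthoc_mean_ranks <- function(values, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  if (k < 2) stop("post-hoc comparison needs at least two groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, labels, mean)
  n_g <- tapply(r, labels, length)
  zcrit <- stats::qnorm(1 - alpha / (k * (k - 1)))
  pairs <- utils::combn(k, 2)
  comp <- data.frame(
    group_i = levels(labels)[pairs[1, ]],
    group_j = levels(labels)[pairs[2, ]],
    obs_diff = abs(mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]]),
    crit_diff = zcrit * sqrt(n * (n + 1) / 12 *
                             (1 / n_g[pairs[1, ]] + 1 / n_g[pairs[2, ]])))
  comp$significant <- comp$obs_diff > comp$crit_diff
  rownames(comp) <- NULL
  letters_vec <- compact_letters(comp$significant, pairs, k,
                                 order(mean_rank))
  list(comparisons = comp,
       letters = stats::setNames(letters_vec, levels(labels)),
       alpha = alpha)
}

# greedy first-fit letter insertion: walk groups in the given order, put each
# into the first letter class containing no group it differs from; open a new
# class when none fits
compact_letters <- function(significant, pairs, k, order_idx) {
  differs <- matrix(FALSE, k, k)
  for (m in seq_len(ncol(pairs))) {
    if (significant[m]) {
      differs[pairs[1, m], pairs[2, m]] <- TRUE
      differs[pairs[2, m], pairs[1, m]] <- TRUE
    }
  }
  classes <- list()
  for (g in order_idx) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(differs[g, classes[[ci]]])) {
        classes[[ci]] <- c(classes[[ci]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1]] <- g
  }
  out <- character(k)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' Write a zone map as an integer raster plus a CSV legend
#' @param zonemap A [cluster_plot()] result.
#' @param summary A [zone_summaries()] result.
#' @param raster_path,legend_path Output paths.
#' @export
write_zone_map <- function(zonemap, summary, raster_path, legend_path) {
  write_raster(zonemap$labels, raster_path, "ascii")
  utils::write.csv(summary$table, legend_path, row.names = FALSE)
  invisible(raster_path)
}
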