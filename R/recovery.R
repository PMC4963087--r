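#' Run the three-plot synthetic recovery study
#'
#' Generates the default synthetic study ([dune_study_scenarios()]), runs the
#' full per-plot analysis ([analyze_plot()]) and the cross-plot harmonization
#' ([harmonize()]), and scores the harmonized partition against the
#' generator's ground-truth zones with the adjusted Rand index.
#'
#' @param seed Base seed for the generator.
#' @param resolution Raster resolution in metres (default 0.5).
#' @param settings A [pipeline_settings()] list; the default restricts the
#'   variogram candidates to the three families with a finite range
#'   (exponential, spherical, gaussian) and scans mixture sizes k = 1..10
#'   (the plateau the method targets begins well below 10), keeping every
#'   other profile value.
#' @param verbose Log stage progress.
#' @return List of class `recovery_study`: `analyses`, `harmonization`,
#'   `scenarios`, `plots` (the generated data), `ari` (harmonized vs truth,
#'   all cells of all plots), `zones_per_plot`, `final_k`,
#'   `max_n_isoscape_plot1` (maximum of the plot-1 N-concentration isoscape),
#'   `highest_cluster_plots` (plots in which the highest-N final cluster
#'   occurs), `highest_cluster_min_dist` (logical: that cluster has the
#'   smallest median canopy distance in every invaded plot).
#' @export
recovery_study <- function(seed = 1L, resolution = 0.5,
                           settings = pipeline_settings(
                             resolution = resolution,
                             models = c("exponential", "spherical", "gaussian"),
                             k_range = 1:10),
                           verbose = FALSE) {
  scen <- dune_study_scenarios(seed = seed, resolution = resolution)
  plots <- lapply(scen, generate_plot)
  analyses <- list(); tables <- list()
  for (pid in names(plots)) {
    pkg_log("analyze plot", pid, verbose = verbose)
    analyses[[pid]] <- suppressWarnings(
      analyze_plot(plots[[pid]]$samples, plots[[pid]]$canopies,
                   extent = scen[[pid]]$extent, settings = settings,
                   verbose = verbose))
    tables[[pid]] <- analyses[[pid]]$summary$table
  }
  harm <- harmonize(tables, k_range = settings$harmonize_k_range)

  truth_all <- unlist(lapply(plots, function(p) raster_values(p$truth)))
  pred_all <- unlist(lapply(names(plots), function(pid)
    raster_values(harmonized_raster(analyses[[pid]]$zonemap, harm, pid))))
  ari <- adjusted_rand_index(truth_all, pred_all)

  # where does the highest-N final cluster occur, and is it the nearest one?
  top <- max(harm$mapping$final_cluster)
  top_plots <- sort(unique(harm$mapping$plot[harm$mapping$final_cluster == top]))
  min_dist_ok <- TRUE
  for (pid in top_plots) {
    tab <- tables[[pid]]
    fc <- harm$mapping$final_cluster[harm$mapping$plot == pid][tab$zone]
    if (all(is.na(tab$median_dist))) { min_dist_ok <- FALSE; next }
    top_med <- min(tab$median_dist[fc == top])
    min_dist_ok <- min_dist_ok && top_med <= min(tab$median_dist) + 1e-9
  }

  structure(list(
    analyses = analyses, harmonization = harm, scenarios = scen, plots = plots,
    ari = ari,
    zones_per_plot = vapply(analyses, function(a) a$zonemap$k, integer(1)),
    final_k = harm$k,
    max_n_isoscape_plot1 = max(raster_values(analyses[["1"]]$isoscapes$n_conc$prediction)),
    highest_cluster_plots = top_plots,
    highest_cluster_min_dist = min_dist_ok
  ), class = "recovery_study")
}

#' Consistency of BIC model-size selection on well-separated mixtures
#'
#' For each seed, draws three well-separated spherical Gaussian components in
#' three dimensions, runs [fit_family()] and records whether the BIC argmax
#' recovers k = 3.
#'
#' @param n_seeds Number of replicate seeds (default 20).
#' @param n_per Observations per component (default 50).
#' @param base_seed Offset added to the replicate index.
#' @param codes Parameterizations to scan (default: all ten).
#' @return Proportion of seeds recovering the generating k.
#' @export
bic_recovery_rate <- function(n_seeds = 20, n_per = 50, base_seed = 100L,
                              codes = parameterizations()) {
  hits <- vapply(seq_len(n_seeds), function(i) {
    set.seed(base_seed + i)
    centers <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 6))
    X <- do.call(rbind, lapply(1:3, function(j)
      matrix(stats::rnorm(n_per * 3, sd = 0.7), ncol = 3) +
        rep(centers[j, ], each = n_per)))
    surf <- suppressWarnings(fit_family(X, k_range = 1:5, codes = codes))
    best_fit(surf)$k == 3L
  }, logical(1))
  mean(hits)
}

#' Consistency of cross-validated variogram family selection
#'
#' For each seed, simulates a Gaussian random field from a spherical
#' variogram at irregular sample locations, runs the LOO-CV selection with
#' spherical and gaussian candidates, and records which family wins.
#'
#' @param n_seeds Number of replicate seeds (default 20).
#' @param n_samples Sample locations per replicate (default 50).
#' @param base_seed Offset added to the replicate index.
#' @return Proportion of seeds in which the spherical family is selected.
#' @export
variogram_selection_rate <- function(n_seeds = 20, n_samples = 50,
                                     base_seed = 500L) {
  model <- variogram_model("spherical", nugget = 0.05, psill = 0.95, range = 8)
  cutoff <- default_cutoff(plot_extent(x_max = 20, y_max = 50))
  hits <- vapply(seq_len(n_seeds), function(i) {
    set.seed(base_seed + i)
    pts <- cbind(stats::runif(n_samples, 0, 20), stats::runif(n_samples, 0, 50))
    z <- simulate_field_at(pts, model, seed = base_seed + i)
    sel <- select_interpolation_model(pts[, 1], pts[, 2], z,
                                      models = c("spherical", "gaussian"),
                                      segmentations = list(uniform_lags(1.2, cutoff)),
                                      cutoff = cutoff, n_restarts = 2)
    sel$model$model == "spherical"
  }, logical(1))
  mean(hits)
}
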