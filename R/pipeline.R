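#' Analysis settings (the "dune2016" profile)
#'
#' The default profile bakes in the published analysis choices: 0.5 m raster
#' resolution, cutoff = one third of the longest plot diagonal, the six
#' candidate lag segmentations, the full variogram model set, all ten
#' covariance parameterizations with k = 1..20 and plateau threshold
#' tau = 0.01, post-hoc alpha = 0.05. Any field can be overridden.
#'
#' @param profile Profile name; only `"dune2016"` is defined.
#' @param ... Named overrides of the fields below.
#' @return A list of settings: `resolution`, `models`, `segmentations`
#'   (`NULL` = the standard six for the plot's cutoff), `cutoff` (`NULL` =
#'   default rule), `min_neighbours`, `cv_restarts`, `codes`, `k_range`,
#'   `tau`, `tol`, `max_iter`, `alpha`, `harmonize_k_range`.
#' @export
pipeline_settings <- function(profile = "dune2016", ...) {
  if (!identical(profile, "dune2016")) {
    stop("unknown profile: ", profile, call. = FALSE)
  }
  s <- list(profile = profile,
            resolution = 0.5,
            models = variogram_models(),
            segmentations = NULL,
            cutoff = NULL,
            min_neighbours = 8,
            cv_restarts = 5,
            codes = parameterizations(),
            k_range = 1:20,
            tau = 0.01,
            tol = 1e-8,
            max_iter = 1000,
            alpha = 0.05,
            harmonize_k_range = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(s))
  if (length(unknown)) {
    stop("unknown setting(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  s[names(dots)] <- dots
  s
}

#' Analyze one plot: interpolate, cluster, summarize
#'
#' Runs the per-plot stages of the method on in-memory inputs: selects a
#' variogram model and lag segmentation per tracer by LOO-CV, kriges the
#' three tracers onto the plot grid, clusters the stacked isoscapes with the
#' constrained mixture family (BIC plateau), and summarizes zones (with
#' canopy-distance medians where canopies exist).
#'
#' @param samples A `sample_table` (see [read_samples()]).
#' @param canopies A [canopy_set()] or `NULL`/empty for uninvaded plots.
#' @param extent A [plot_extent()]; default: the 20 x 50 m plot at origin.
#' @param settings A [pipeline_settings()] list.
#' @param verbose Log stage progress.
#' @return List of class `plot_analysis` with `isoscapes` (per tracer),
#'   `selection` (per-tracer CV reports), `stack`, `zonemap`, `summary`,
#'   `distance`, `cutoff`, `grid`.
#' @export
analyze_plot <- function(samples, canopies = NULL,
                         extent = plot_extent(x_max = 20, y_max = 50),
                         settings = pipeline_settings(), verbose = FALSE) {
  stopifnot(inherits(samples, "sample_table"))
  grid <- plot_grid(extent, settings$resolution)
  cutoff <- if (is.null(settings$cutoff)) default_cutoff(extent) else settings$cutoff
  segs <- if (is.null(settings$segmentations)) {
    standard_segmentations(cutoff)
  } else settings$segmentations

  isoscapes <- list(); selection <- list()
  for (tr in c("n_conc", "d15N", "d13C")) {
    pkg_log("interpolate", tr, verbose = verbose)
    sel <- select_interpolation_model(samples$x, samples$y, samples[[tr]],
                                      models = settings$models,
                                      segmentations = segs, cutoff = cutoff,
                                      n_restarts = settings$cv_restarts)
    iso <- ordinary_krige(samples$x, samples$y, samples[[tr]], sel$model,
                          grid, cutoff = cutoff,
                          min_neighbours = settings$min_neighbours,
                          units = if (tr == "n_conc") "g N/kg" else "permil")
    isoscapes[[tr]] <- iso
    selection[[tr]] <- sel
  }

  distance <- NULL
  if (!is.null(canopies) && length(canopies$polygons)) {
    canopy_r <- rasterize_canopy(canopies, grid)
    if (any(canopy_r$values)) distance <- distance_to_canopy(canopy_r)
  }

  pkg_log("cluster", verbose = verbose)
  stack <- stack_isoscapes(isoscapes$n_conc, isoscapes$d15N, isoscapes$d13C)
  zonemap <- cluster_plot(stack, k_range = settings$k_range,
                          codes = settings$codes, tau = settings$tau,
                          tol = settings$tol, max_iter = settings$max_iter,
                          verbose = verbose)
  summary <- zone_summaries(zonemap, stack, distance = distance,
                            alpha = settings$alpha)
  structure(list(isoscapes = isoscapes, selection = selection,
                 stack = stack, zonemap = zonemap, summary = summary,
                 distance = distance, cutoff = cutoff, grid = grid),
            class = "plot_analysis")
}

#' Run the full multi-plot pipeline from a configuration
#'
#' Pre-flight checks all input paths, runs [analyze_plot()] for every plot,
#' harmonizes zones across plots with [harmonize()], writes all artifacts
#' (isoscapes, zone rasters, legends, selection reports, BIC surfaces,
#' dendrogram, mapping) under `config$out_dir` and returns (and writes) a run
#' manifest with per-stage selected models and md5 checksums of every output.
#'
#' @param config A list as returned by [read_run_config()] — fields `plots`
#'   (list of `list(id, samples, canopies)` paths), `out_dir`, `seed`, plus
#'   any [pipeline_settings()] overrides — or a path to a YAML config.
#' @param verbose Log stage progress.
#' @return The manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$plots), !is.null(config$out_dir))
  # pre-flight: every referenced path must exist before any computation
  for (p in config$plots) {
    if (!file.exists(p$samples)) {
      stop("pre-flight: samples file not found for plot ", p$id, ": ",
           p$samples, call. = FALSE)
    }
    if (!is.null(p$canopies) && !file.exists(p$canopies)) {
      stop("pre-flight: canopy file not found for plot ", p$id, ": ",
           p$canopies, call. = FALSE)
    }
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  override <- config[setdiff(names(config),
                             c("plots", "out_dir", "seed", "profile", "version"))]
  settings <- do.call(pipeline_settings,
                      c(list(profile = if (is.null(config$profile))
                               "dune2016" else config$profile),
                        override))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  analyses <- list(); tables <- list(); warns <- character(0)
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }
  for (p in config$plots) {
    pid <- as.character(p$id)
    pkg_log("plot", pid, verbose = verbose)
    samples <- read_samples(p$samples)
    canopies <- if (!is.null(p$canopies)) read_canopies(p$canopies) else NULL
    extent <- if (!is.null(p$extent)) {
      do.call(plot_extent, as.list(p$extent))
    } else plot_extent(x_max = 20, y_max = 50)
    an <- withCallingHandlers(
      analyze_plot(samples, canopies, extent, settings, verbose = verbose),
      warning = function(w) {
        warns <<- c(warns, paste0("plot ", pid, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    analyses[[pid]] <- an
    tables[[pid]] <- an$summary$table
    base <- file.path(config$out_dir, paste0("plot", pid))
    for (tr in names(an$isoscapes)) {
      write_raster(an$isoscapes[[tr]]$prediction,
                   emit(paste0(base, "_", tr, ".asc")), "ascii")
      utils::write.csv(an$selection[[tr]]$report,
                       emit(paste0(base, "_", tr, "_cv.csv")), row.names = FALSE)
    }
    write_bic_surface(an$zonemap$surface, emit(paste0(base, "_bic.csv")))
    write_zone_map(an$zonemap, an$summary, emit(paste0(base, "_zones.asc")),
                   emit(paste0(base, "_zones_legend.csv")))
    if (!is.null(an$distance)) {
      write_raster(an$distance, emit(paste0(base, "_distance.asc")), "ascii")
    }
  }

  pkg_log("harmonize", verbose = verbose)
  harm <- harmonize(tables, k_range = settings$harmonize_k_range)
  write_newick(harm$tree, emit(file.path(config$out_dir, "dendrogram.nwk")))
  utils::write.csv(harm$mapping,
                   emit(file.path(config$out_dir, "harmonization.csv")),
                   row.names = FALSE)
  for (pid in names(analyses)) {
    fr <- harmonized_raster(analyses[[pid]]$zonemap, harm, pid)
    write_raster(fr, emit(file.path(config$out_dir,
                                    paste0("plot", pid, "_final.asc"))), "ascii")
  }

  manifest <- list(
    package = "isozone",
    version = as.character(utils::packageVersion("isozone")),
    profile = settings$profile,
    seed = seed,
    resolution = settings$resolution,
    tau = settings$tau,
    config = local({
      echo <- config[setdiff(names(config), "out_dir")]
      if (!is.null(echo$segmentations)) {
        echo$segmentations <- lapply(echo$segmentations, function(s)
          list(label = s$label, boundaries = s$boundaries))
      }
      echo
    }),
    plots = lapply(names(analyses), function(pid) {
      an <- analyses[[pid]]
      list(id = pid,
           variograms = lapply(an$selection, function(s)
             list(model = s$model$model, segmentation = s$segmentation$label,
                  rmse = s$cv$rmse, r_squared = s$cv$r_squared)),
           mixture = list(code = an$zonemap$code, k = an$zonemap$k,
                          tau = an$zonemap$tau))
    }),
    final_k = harm$k,
    silhouette = as.list(harm$silhouette),
    warnings = warns,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$plots) <- names(analyses)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), manifest_path)
  manifest$analyses <- analyses
  manifest$harmonization <- harm
  invisible(manifest)
}

#' Read a YAML run configuration
#'
#' Schema (version 1): `plots` (list of `id`, `samples`, optional `canopies`,
#' optional `extent` with x_min/y_min/x_max/y_max), `out_dir`, `seed`,
#' optional `profile` and any [pipeline_settings()] override.
#'
#' @param path YAML file.
#' @return The config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$version) && cfg$version != 1) {
    stop("unsupported config schema version: ", cfg$version, call. = FALSE)
  }
  cfg
}

#' Write a generated synthetic study to pipeline input files
#'
#' Materializes [generate_plot()] outputs in the same CSV/GeoJSON dialects the
#' pipeline reads, plus truth rasters, and returns a ready-to-run config.
#'
#' @param scenarios Named list of [plot_scenario()]s
#'   (e.g. [dune_study_scenarios()]).
#' @param dir Output directory.
#' @param seed Seed recorded in the config.
#' @return A config list suitable for [run_pipeline()].
#' @export
write_synthetic_study <- function(scenarios, dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plots <- list()
  for (pid in names(scenarios)) {
    sp <- generate_plot(scenarios[[pid]])
    s_path <- file.path(dir, paste0("plot", pid, "_samples.csv"))
    write_samples(sp$samples, s_path)
    c_path <- NULL
    if (length(sp$canopies$polygons)) {
      c_path <- file.path(dir, paste0("plot", pid, "_canopies.geojson"))
      write_canopies(sp$canopies, c_path)
    }
    write_raster(sp$truth, file.path(dir, paste0("plot", pid, "_truth.asc")),
                 "ascii")
    e <- scenarios[[pid]]$extent
    plots[[pid]] <- list(id = pid, samples = s_path, canopies = c_path,
                         extent = list(x_min = e$x_min, y_min = e$y_min,
                                       x_max = e$x_max, y_max = e$y_max))
  }
  list(version = 1, profile = "dune2016", seed = seed,
       out_dir = file.path(dir, "out"), plots = unname(plots))
}
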