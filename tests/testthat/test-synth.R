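test_that("influence kernels have the stated shapes", {
  k <- influence_kernel("exp_decay", amplitude = 7, lambda_d = 3)
  expect_equal(kernel_value(k, 0), 7)
  expect_lt(kernel_value(k, 5 * 3 + 0.01), 0.01 * 7)
  d <- seq(0, 30, by = 0.1)
  expect_true(all(diff(kernel_value(k, d)) <= 0))  # monotone decreasing

  # hump: peak location has the closed form ld*l2/(l2-ld)*log(l2/ld)
  kh <- influence_kernel("hump", amplitude = 2.5, lambda_d = 1.5, lambda2 = 5)
  dstar <- 1.5 * 5 / (5 - 1.5) * log(5 / 1.5)
  expect_equal(kernel_value(kh, dstar), 2.5, tolerance = 1e-9)
  opt <- optimize(function(d) -kernel_value(kh, d), c(0, 30))
  expect_equal(opt$minimum, dstar, tolerance = 1e-5)
  expect_equal(kernel_value(kh, 0), 0)
  expect_lt(kernel_value(kh, 0), 2.5)            # f(0) < peak

  # depression shifts the canopy-core value below background
  kd <- influence_kernel("hump", amplitude = 2.5, lambda_d = 1.5, lambda2 = 5,
                         depression = 1)
  expect_equal(kernel_value(kd, 0), -1, tolerance = 1e-9)
  expect_equal(-optimize(function(d) -kernel_value(kd, d), c(0, 30))$objective,
               2.5, tolerance = 1e-6)

  expect_error(influence_kernel("hump", 2.5, lambda_d = 5, lambda2 = 3),
               "lambda2 > lambda_d")
  expect_error(kernel_value(k, c(1, NA)), "finite")
})

test_that("Gaussian random fields honour seed, sill and variogram", {
  g <- plot_grid(plot_extent(x_max = 10, y_max = 10), 1)
  # zero sill: constant zero field
  f0 <- gaussian_random_field(g, variogram_model("nugget", 0, 0), seed = 1)
  expect_true(all(f0$values == 0))
  # determinism
  m <- variogram_model("spherical", 0.1, 0.9, 8)
  f1 <- gaussian_random_field(g, m, seed = 9)
  f2 <- gaussian_random_field(g, m, seed = 9)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values,
                         gaussian_random_field(g, m, seed = 10)$values))
  # unbounded models cannot define a field covariance
  expect_error(gaussian_random_field(g, variogram_model("power", 0, 1, p = 1.5)),
               "finite sill")
  expect_error(gaussian_random_field(plot_grid(plot_extent(x_max = 200, y_max = 200), 1), m),
               "too large")

  # per-field variance is close to the unit sill on a 20 x 50 m domain
  g2 <- plot_grid(plot_extent(x_max = 20, y_max = 50), 2)
  vs <- vapply(1:50, function(s)
    var(raster_values(gaussian_random_field(g2, variogram_model("spherical", 0, 1, 8),
                                            seed = s))), numeric(1))
  expect_gt(mean(vs), 0.8)
  expect_lt(mean(vs), 1.2)
})

test_that("a simulated field's empirical variogram tracks the generating model", {
  g <- plot_grid(plot_extent(x_max = 20, y_max = 50), 1.25)
  m <- variogram_model("spherical", 0.05, 0.95, 8)
  f <- gaussian_random_field(g, m, seed = 4)
  ctr <- grid_centres(g)
  ev <- empirical_variogram(ctr[, 1], ctr[, 2], raster_values(f),
                            uniform_lags(1, 8), 8)
  at_lag <- model_semivariance(m, ev$h)
  inside <- ev$h < 8
  expect_true(all(abs(ev$gamma[inside] - at_lag[inside]) / at_lag[inside] < 0.25))
})

test_that("generated plots are deterministic and respect the null case", {
  scen <- dune_study_scenarios(seed = 3, resolution = 1)
  p1a <- generate_plot(scen[["1"]])
  p1b <- generate_plot(scen[["1"]])
  expect_identical(p1a$samples, p1b$samples)     # byte-identical under a seed
  expect_equal(nrow(p1a$samples), 100)           # 2 x 5 m lattice on 20 x 50

  # null influence: tracers uncorrelated with canopy distance
  base <- scen[["1"]]
  cors <- vapply(1:10, function(s) {
    null_sc <- plot_scenario(
      canopies = base$canopies,
      n_conc = tracer_spec(6, base$tracers$n_conc$field, NULL, 0.5),
      d15N = tracer_spec(-11, base$tracers$d15N$field, NULL, 0.2),
      d13C = tracer_spec(-27, base$tracers$d13C$field, NULL, 0.1),
      resolution = 1, seed = 7000L + s)
    sp <- generate_plot(null_sc)
    cr <- rasterize_canopy(sp$canopies, sp$grid)
    occ <- grid_centres(sp$grid)[raster_values(cr), , drop = FALSE]
    d <- vapply(seq_len(nrow(sp$samples)), function(i)
      sqrt(min((sp$samples$x[i] - occ[, 1])^2 + (sp$samples$y[i] - occ[, 2])^2)),
      numeric(1))
    cor(sp$samples$n_conc, d)
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.2)
})

test_that("invaded scenarios reproduce the field-scale effect magnitudes", {
  scen <- dune_study_scenarios(seed = 5, resolution = 1)
  sp <- generate_plot(scen[["1"]])
  pts <- cbind(sp$samples$x, sp$samples$y)
  under <- rep(FALSE, nrow(pts))
  for (p in sp$canopies$polygons) {
    under <- under | mgcv::in.out(rbind(p, p[1, ]), pts)
  }
  occ <- grid_centres(sp$grid)[raster_values(sp$distance) == 0, , drop = FALSE]
  d <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((pts[i, 1] - occ[, 1])^2 + (pts[i, 2] - occ[, 2])^2)), numeric(1))
  # delta-15N approaches atmospheric 0 permil under the canopy
  expect_lt(abs(mean(sp$samples$d15N[under])), 1)
  # N concentration more than doubles relative to the uninfluenced background
  bg_median <- median(sp$samples$n_conc[!under & d > 9])
  expect_gte(median(sp$samples$n_conc[under]), 2 * bg_median)

  # truth zones: canopy core only where canopies exist; uninvaded all background
  expect_setequal(unique(raster_values(sp$truth)), c(1, 2, 3))
  p3 <- generate_plot(scen[["3"]])
  expect_identical(unique(raster_values(p3$truth)), 1)
  expect_null(p3$distance)

  # canopy covering everything is rejected
  full <- plot_scenario(
    extent = plot_extent(x_max = 10, y_max = 10), subplot_w = 2, subplot_h = 5,
    canopies = canopy_set(list(rbind(c(-1, -1), c(11, -1), c(11, 11), c(-1, 11)))),
    n_conc = scen[["1"]]$tracers$n_conc, d15N = scen[["1"]]$tracers$d15N,
    d13C = scen[["1"]]$tracers$d13C, resolution = 1, seed = 1)
  expect_error(generate_plot(full), "whole plot")
})
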