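test_that("default cutoff is one third of the longest diagonal", {
  expect_equal(round(default_cutoff(plot_extent(x_max = 20, y_max = 50)), 2), 17.95)
  expect_equal(default_cutoff(plot_extent(x_max = 30, y_max = 40)), 50 / 3)
  expect_error(plot_extent(x_max = 0, y_max = 50), "degenerate")
})

test_that("empirical variogram equals brute-force pair enumeration", {
  # constant field: all semivariances zero
  ev0 <- empirical_variogram(1:10, rep(0, 10), rep(4, 10), uniform_lags(2, 10), 10)
  expect_true(all(ev0$gamma == 0))

  # two samples 1 m apart with values 0 and 2: gamma = (1/2) * 2^2 / 1 = 2
  ev2 <- empirical_variogram(c(0, 1), c(0, 0), c(0, 2), uniform_lags(2, 5), 5)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$gamma, 2)
  expect_equal(ev2$np, 1L)

  # 50 random points, uniform 2 m bins, vs exhaustive enumeration
  set.seed(11)
  x <- runif(50, 0, 20); y <- runif(50, 0, 50); z <- rnorm(50)
  seg <- uniform_lags(2, 18)
  ev <- empirical_variogram(x, y, z, seg, 18)
  bf <- brute_variogram(x, y, z, seg$boundaries, 18)
  expect_equal(ev$h, bf$h)
  expect_equal(ev$gamma, bf$gamma)
  expect_equal(ev$np, bf$np)

  expect_error(empirical_variogram(c(0, 30), c(0, 0), c(1, 2),
                                   uniform_lags(2, 10), 10), "no pairs")
})

test_that("model semivariance has the stated closed forms", {
  sph <- variogram_model("spherical", 0, 1, 10)
  expect_equal(model_semivariance(sph, 10), 1)           # sill at range
  expect_equal(model_semivariance(sph, 5), 1.5 * 0.5 - 0.5 * 0.125)
  expo <- variogram_model("exponential", 0, 1, 1)
  expect_equal(model_semivariance(expo, 1), 1 - exp(-1))
  for (m in variogram_models()) {
    vm <- variogram_model(m, nugget = 0.2, psill = 1, range = 3, p = 1.5)
    expect_equal(model_semivariance(vm, 0), 0)           # gamma(0) = 0 always
    h <- seq(0.01, 20, by = 0.01)
    expect_true(all(diff(model_semivariance(vm, h)) >= -1e-12))  # nondecreasing
  }
  expect_error(model_semivariance(sph, -1), "negative")
})

test_that("WLS variogram fitting recovers noise-free parameters", {
  m_true <- variogram_model("spherical", 0.1, 0.9, 8)
  h <- seq(0.5, 15, by = 0.5)
  emp <- structure(data.frame(h = h, gamma = model_semivariance(m_true, h),
                              np = 50L),
                   class = c("empirical_variogram", "data.frame"))
  set.seed(3)
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-6)
  expect_equal(fit$psill, 0.9, tolerance = 1e-6)
  expect_equal(fit$range, 8, tolerance = 1e-6)

  # flat empirical variogram -> pure nugget
  emp_flat <- structure(data.frame(h = c(2, 5, 9, 14), gamma = 0.7, np = 20L),
                        class = c("empirical_variogram", "data.frame"))
  set.seed(4)
  f2 <- fit_variogram(emp_flat, "exponential")
  expect_equal(f2$nugget + model_semivariance(f2, 14), 0.7 + f2$nugget,
               tolerance = 0.05)  # fitted curve is flat at 0.7
  expect_equal(model_semivariance(f2, 5), model_semivariance(f2, 14),
               tolerance = 0.02)

  emp2 <- structure(data.frame(h = c(1, 2), gamma = c(0.5, 0.6), np = 5L),
                    class = c("empirical_variogram", "data.frame"))
  expect_error(fit_variogram(emp2, "spherical"), "too few")
})

test_that("ordinary kriging solves the hand-checkable systems", {
  g <- plot_grid(plot_extent(x_max = 4, y_max = 4), 1)
  # unbiasedness: constant data predicts the constant everywhere
  iso_c <- ordinary_krige(c(0.5, 2.1, 3.3), c(0.7, 1.9, 3.6), c(5, 5, 5),
                          variogram_model("exponential", 0, 1, 2), g)
  expect_equal(as.vector(iso_c$prediction$values), rep(5, 16), tolerance = 1e-10)

  # pure nugget, two samples {1, 3}: equal weights, prediction 2
  kw <- kriging_weights(c(0, 2), c(0, 0), c(1, 3),
                        variogram_model("nugget", nugget = 1, psill = 0), 5, 5)
  expect_equal(kw$weights, c(0.5, 0.5))
  expect_equal(kw$prediction, 2)

  # zero nugget: exact interpolation and zero variance at sample cells
  s <- list(x = c(0.5, 2.5, 3.5), y = c(0.5, 1.5, 3.5), z = c(1, 5, 9))
  iso <- ordinary_krige(s$x, s$y, s$z, variogram_model("exponential", 0, 1, 3), g)
  expect_equal(iso$prediction$values[1, 1], 1)
  expect_equal(iso$prediction$values[2, 3], 5)
  expect_equal(iso$variance$values[1, 1], 0)
  expect_true(all(iso$variance$values[4, c(1, 2)] > 0))
  expect_error(ordinary_krige(c(1, 1), c(2, 2), c(1, 2),
                              variogram_model("exponential", 0, 1, 3), g),
               "duplicate")
})

test_that("kriging weights sum to one at every cell", {
  set.seed(21)
  g <- plot_grid(plot_extent(x_max = 10, y_max = 10), 1)
  x <- runif(15, 0, 10); y <- runif(15, 0, 10); z <- rnorm(15)
  for (mdl in list(variogram_model("spherical", 0.1, 1, 5),
                   variogram_model("gaussian", 0.05, 1, 3))) {
    ctr <- grid_centres(g)
    for (i in sample(nrow(ctr), 20)) {
      kw <- kriging_weights(x, y, z, mdl, ctr[i, 1], ctr[i, 2])
      expect_lt(abs(sum(kw$weights) - 1), 1e-10)
    }
    # predictions stay within the data range when all weights are non-negative
    iso <- ordinary_krige(x, y, z, mdl, g)
    kw_all <- sapply(seq_len(nrow(ctr)), function(i)
      all(kriging_weights(x, y, z, mdl, ctr[i, 1], ctr[i, 2])$weights >= -1e-10))
    p <- raster_values(iso$prediction)
    expect_true(all(p[kw_all] >= min(z) - 1e-8 & p[kw_all] <= max(z) + 1e-8))
  }
})

test_that("LOO cross-validation and model selection behave as specified", {
  # degenerate constant field: perfect predictions, undefined R^2
  st <- make_samples(20, seed = 2)
  cv0 <- loo_cross_validate(st$x, st$y, rep(7, 20), "nugget",
                            uniform_lags(4, 18), 18)
  expect_equal(cv0$rmse, 0, tolerance = 1e-9)
  expect_true(is.na(cv0$r_squared))

  expect_error(loo_cross_validate(1:3, 1:3, 1:3, "nugget",
                                  uniform_lags(2, 5), 5), "at least four")

  # the standard candidate grid has six segmentations
  segs <- standard_segmentations(default_cutoff(plot_extent(x_max = 20, y_max = 50)))
  expect_equal(length(segs), 6)
  expect_equal(segs[["non-uniform"]]$boundaries, c(1, 2, 3, 4, 5, 6, 7, 9, 12, 15, 18))

  # selection returns the minimum-RMSE convergent candidate of its own report
  set.seed(9)
  sel <- select_interpolation_model(st$x, st$y, st$d15N,
                                    models = c("nugget", "exponential"),
                                    segmentations = segs[c(3, 5)],
                                    cutoff = 17.95, n_restarts = 2)
  rep_ok <- subset(sel$report, converged)
  expect_equal(sel$report$rmse[sel$report$chosen], min(rep_ok$rmse))
  expect_s3_class(sel$model, "variogram_model")
  # a 3-parameter model on a 2-bin segmentation can never converge
  expect_error(select_interpolation_model(st$x, st$y, st$d15N,
                                          models = "spherical",
                                          segmentations = list(uniform_lags(9, 18)),
                                          cutoff = 18),
               "no convergent")
})
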