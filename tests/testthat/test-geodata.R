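test_that("sample tables read, validate and reject malformed input", {
  df <- data.frame(x = c(1, 3, 5), y = c(2, 4, 6),
                   n_conc = c(6, 7, 8), d15N = c(-10, -8, -6),
                   d13C = c(-27, -26.5, -26))
  st <- read_samples(write_samples_csv(df))
  expect_s3_class(st, "sample_table")
  expect_equal(nrow(st), 3)
  expect_equal(st$d15N, df$d15N)

  # column mapping onto foreign names
  df2 <- df
  names(df2) <- c("easting", "northing", "N", "dN", "dC")
  st2 <- read_samples(write_samples_csv(df2),
                      columns = c(x = "easting", y = "northing", n_conc = "N",
                                  d15N = "dN", d13C = "dC"))
  expect_equal(st2$n_conc, df$n_conc)

  # missing column -> schema error naming it
  expect_error(read_samples(write_samples_csv(df[, -5])), "d13C")
  # non-numeric tracer -> parse error with row number
  df3 <- df; df3$d15N <- c("-10", "oops", "-6")
  expect_error(read_samples(write_samples_csv(df3)), "row 2")
  # duplicated coordinates -> validation error
  df4 <- rbind(df, df[1, ])
  expect_error(read_samples(write_samples_csv(df4)), "duplicated")
  # missing tracer value -> rejected
  df5 <- df; df5$d13C[2] <- NA
  expect_error(read_samples(write_samples_csv(df5)), "missing")
})

test_that("grid geometry follows the cell-centre convention", {
  g <- plot_grid(plot_extent(x_max = 20, y_max = 50), 0.5)
  expect_equal(g$n_cols, 40)
  expect_equal(g$n_rows, 100)
  ctr <- grid_centres(g)
  expect_equal(nrow(ctr), 4000)
  expect_equal(ctr[1, ], c(x = 0.25, y = 0.25))
  expect_true(all(ctr[, 1] > 0 & ctr[, 1] < 20))
  expect_true(all(ctr[, 2] > 0 & ctr[, 2] < 50))
  expect_error(plot_extent(x_max = 0, y_max = 50), "degenerate")
  expect_error(plot_grid(plot_extent(x_max = 1, y_max = 1), -1), "positive")
})

test_that("canopy rasterization matches brute-force centre containment", {
  g <- plot_grid(plot_extent(x_max = 10, y_max = 10), 1)
  # square covering cell centres (0..3, 0..3)
  sq <- canopy_set(list(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))))
  r <- rasterize_canopy(sq, g)
  expect_identical(sum(r$values), 16L)
  ctr <- grid_centres(g)
  brute <- ctr[, 1] > 0 & ctr[, 1] < 4 & ctr[, 2] > 0 & ctr[, 2] < 4
  expect_equal(raster_values(r) > 0.5, unname(brute))

  # empty set and fully-outside polygon give all-false rasters
  expect_false(any(rasterize_canopy(canopy_set(), g)$values))
  out <- canopy_set(list(rbind(c(20, 20), c(25, 20), c(25, 25), c(20, 25))))
  expect_false(any(rasterize_canopy(out, g)$values))

  # true-cell area converges to polygon area with refinement
  rect <- canopy_set(list(rbind(c(1.2, 1.3), c(7.8, 1.3), c(7.8, 6.1), c(1.2, 6.1))))
  area_true <- canopy_area(rect)
  err <- sapply(c(1, 0.25), function(res) {
    rr <- rasterize_canopy(rect, plot_grid(plot_extent(x_max = 10, y_max = 10), res))
    abs(sum(rr$values) * res^2 - area_true)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2] / area_true, 0.05)

  expect_error(canopy_set(list(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)))),
               "self-intersecting")
})

test_that("distance transform equals exhaustive nearest-cell search", {
  g <- plot_grid(plot_extent(x_max = 10, y_max = 10), 1)
  # single canopy cell centred at (5.5, 5.5) via a tiny square
  one <- rasterize_canopy(canopy_set(list(rbind(c(5, 5), c(6, 5), c(6, 6), c(5, 6)))), g)
  expect_identical(sum(one$values), 1L)
  d <- distance_to_canopy(one)
  expect_equal(d$values[6, 6], 0)              # inside canopy
  expect_equal(d$values[10, 9], 5)             # 3-4-5 triangle from (8.5, 9.5)

  # random 20 x 20 mask vs O(cells^2) brute force
  set.seed(7)
  g2 <- plot_grid(plot_extent(x_max = 20, y_max = 20), 1)
  mask <- matrix(runif(400) < 0.05, 20, 20)
  cr <- raster_layer(g2, mask)
  dd <- distance_to_canopy(cr)
  ctr <- grid_centres(g2)
  occ <- ctr[raster_values(cr), , drop = FALSE]
  brute <- apply(ctr, 1, function(p) sqrt(min((p[1] - occ[, 1])^2 + (p[2] - occ[, 2])^2)))
  expect_equal(raster_values(dd), unname(brute), tolerance = 1e-12)

  # monotone: adding canopy cells never increases any distance
  mask2 <- mask; mask2[3, 17] <- TRUE
  d2 <- distance_to_canopy(raster_layer(g2, mask2))
  expect_true(all(d2$values <= dd$values + 1e-12))

  expect_warning(dn <- distance_to_canopy(raster_layer(g2, mask & FALSE)),
                 "uninvaded")
  expect_true(all(is.na(dn$values)))
})

test_that("raster writers round-trip values, grid and missing mask", {
  g <- plot_grid(plot_extent(2, 3, 12, 8), 0.5)
  set.seed(5)
  v <- matrix(rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
  v[2, 3] <- NA
  r <- raster_layer(g, v, units = "permil")
  f <- tempfile(fileext = ".asc")
  write_raster(r, f, "ascii")
  r2 <- read_raster(f)
  expect_identical(r2$values, r$values)      # bit-identical
  expect_true(same_grid <- isTRUE(all.equal(r2$grid$extent$x_min, 2)))
  expect_equal(r2$grid$n_rows, g$n_rows)
  expect_equal(r2$units, "permil")

  # tiff + world file preserves grid metadata (values at single precision)
  ft <- tempfile(fileext = ".tif")
  write_raster(r, ft, "tiff")
  r3 <- read_raster(ft)
  expect_equal(r3$grid$n_rows, g$n_rows)
  expect_equal(r3$grid$resolution, 0.5)
  expect_equal(r3$grid$extent$x_min, 2)
  expect_equal(r3$grid$extent$y_min, 3)
  expect_equal(r3$values, r$values, tolerance = 1e-6)
  expect_identical(is.na(r3$values), is.na(r$values))

  expect_error(write_raster(r, f, "netcdf"), "ascii, tiff")
  expect_error(write_raster(r, file.path(tempdir(), "no/such/dir/x.asc"), "ascii"))
})

test_that("canopy polygons round-trip through GeoJSON and parse from WKT", {
  polys <- canopy_set(list(rbind(c(2, 34), c(11, 34), c(11, 47), c(2, 47)),
                           rbind(c(13, 5), c(19, 5), c(19, 13), c(13, 13))))
  f <- tempfile(fileext = ".geojson")
  write_canopies(polys, f)
  back <- read_canopies(f)
  expect_equal(length(back$polygons), 2)
  expect_equal(canopy_area(back), canopy_area(polys))

  fw <- tempfile(fileext = ".wkt")
  writeLines(c("POLYGON ((0 0, 4 0, 4 4, 0 4, 0 0))",
               "MULTIPOLYGON (((5 5, 7 5, 7 7, 5 7, 5 5)))"), fw)
  w <- read_canopies(fw)
  expect_equal(length(w$polygons), 2)
  expect_equal(canopy_area(w), 16 + 4)
})
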