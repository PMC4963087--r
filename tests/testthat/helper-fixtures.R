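# shared fixture builders for the test suite; everything is generated in code

# small irregular sample table with smooth spatial structure
make_samples <- function(n = 30, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, 20)
  y <- runif(n, 0, 50)
  as_sample_table(data.frame(
    x = x, y = y,
    n_conc = 6 + 0.1 * x + 0.05 * y + rnorm(n, 0, 0.2),
    d15N = -10 + 0.08 * y + rnorm(n, 0, 0.3),
    d13C = -27 + 0.05 * x + rnorm(n, 0, 0.1)))
}

write_samples_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# brute-force empirical variogram: O(n^2) pair enumeration
brute_variogram <- function(x, y, z, boundaries, cutoff) {
  n <- length(x)
  h <- g <- np <- numeric(length(boundaries))
  sums <- dsum <- cnt <- numeric(length(boundaries))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d > cutoff || d <= 0) next
      b <- which(d <= pmin(boundaries, cutoff))[1]
      if (is.na(b)) next
      sums[b] <- sums[b] + (z[i] - z[j])^2
      dsum[b] <- dsum[b] + d
      cnt[b] <- cnt[b] + 1
    }
  }
  keep <- cnt > 0
  out <- data.frame(h = dsum[keep] / cnt[keep],
                    gamma = sums[keep] / (2 * cnt[keep]),
                    np = as.integer(cnt[keep]))
  out[order(out$h), ]
}

# a small three-column matrix with three well-separated Gaussian blobs
make_blobs <- function(n_per = 50, centers = rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 6)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j)
    matrix(rnorm(n_per * 3, sd = sd), ncol = 3) + rep(centers[j, ], each = n_per)))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# deterministic raster stack with two blocks of distinct tracer values
make_two_zone_stack <- function(nr = 10, nc = 10, noise = 0.05, seed = 42) {
  set.seed(seed)
  g <- plot_grid(plot_extent(x_max = nc, y_max = nr), 1)
  zone <- matrix(1L, nr, nc)
  zone[, seq_len(nc / 2)] <- 2L  # left half high-N
  mk <- function(lo, hi, units) {
    v <- ifelse(zone == 2L, hi, lo) + matrix(rnorm(nr * nc, 0, noise), nr, nc)
    raster_layer(g, v, units = units)
  }
  list(stack = stack_isoscapes(mk(6, 12, "g N/kg"),
                               mk(-10, -1, "permil"),
                               mk(-27, -25, "permil")),
       truth = as.vector(t(zone)))
}
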