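test_that("free-parameter counts follow the constraint patterns", {
  expect_identical(n_params("VVV", 3, 3), 29L)  # 2 + 9 + 3*6
  expect_identical(n_params("EII", 1, 1), 2L)   # mean + one variance
  expect_identical(n_params("EEE", 4, 3), 21L)  # 3 + 12 + 6 shared
  expect_identical(n_params("VVI", 2, 3), 1L + 6L + 6L)
  expect_error(n_params("XYZ", 2, 3), "unknown")
})

test_that("single-component fits reduce to closed-form Gaussian MLEs", {
  # d = 1, data {0, 2}: mu = 1, sigma^2 = 1, ll = -n/2 log(2 pi) - n/2
  f <- em_fit(matrix(c(0, 2), ncol = 1), 1, "EII")
  expect_equal(drop(f$mu), 1)
  expect_equal(f$sigma[[1]][1, 1], 1)
  expect_equal(f$loglik, -log(2 * pi) - 1, tolerance = 1e-12)
  expect_equal(f$loglik, -2.837877, tolerance = 1e-6)
  expect_equal(bic(f), 2 * f$loglik - 2 * log(2))
  expect_equal(bic(f), -7.062048, tolerance = 1e-5)

  # d = 3: every code's k=1 loglik matches its covariance-constrained MLE
  set.seed(8)
  X <- matrix(rnorm(90), 30, 3)
  n <- nrow(X)
  S <- cov(X) * (n - 1) / n
  ll_with <- function(S1) {
    -n / 2 * (3 * log(2 * pi) + log(det(S1)) +
                sum(diag(solve(S1) %*% S)))
  }
  cases <- list(
    EII = diag(3) * mean(diag(S)),
    EEI = diag(diag(S)),
    EEE = S)
  for (code in names(cases)) {
    f1 <- em_fit(X, 1, code)
    expect_equal(drop(f1$mu), colMeans(X), tolerance = 1e-12)
    expect_equal(f1$loglik, ll_with(cases[[code]]), tolerance = 1e-8,
                 label = paste("k=1 loglik,", code))
  }
})

test_that("EM log-likelihood is monotone and responsibilities normalized for all ten codes", {
  set.seed(17)
  X <- rbind(matrix(rnorm(120, 0, 1), ncol = 3),
             matrix(rnorm(120, 2.5, 1.3), ncol = 3))
  for (code in parameterizations()) {
    f <- suppressWarnings(em_fit(X, 3, code, tol = 1e-9))
    expect_true(all(diff(f$loglik_trace) >= -1e-7 * abs(f$loglik)),
                label = paste("monotone loglik,", code))
    expect_true(all(abs(rowSums(f$z) - 1) < 1e-12),
                label = paste("responsibility rows,", code))
  }
})

test_that("fitted covariances comply with their constraint patterns", {
  set.seed(23)
  X <- rbind(matrix(rnorm(150, 0, 1), ncol = 3),
             matrix(rnorm(150, 4, 2), ncol = 3))
  vol <- function(S) det(S)^(1 / 3)
  # spherical codes: scalar multiples of the identity
  for (code in c("EII", "VII")) {
    f <- em_fit(X, 2, code)
    for (S in f$sigma) {
      expect_equal(S, diag(S[1, 1], 3), tolerance = 1e-10,
                   label = paste(code, "sphericity"))
    }
  }
  # equal-volume codes share lambda across components
  for (code in c("EII", "EEI", "EVI", "EEE", "EEV")) {
    f <- em_fit(X, 2, code)
    expect_equal(vol(f$sigma[[1]]), vol(f$sigma[[2]]), tolerance = 1e-8,
                 label = paste(code, "equal volume"))
  }
  # EEE: identical covariance in every component
  f <- em_fit(X, 2, "EEE")
  expect_equal(f$sigma[[1]], f$sigma[[2]], tolerance = 1e-12)
  # diagonal codes stay diagonal
  for (code in c("EEI", "VEI", "EVI", "VVI")) {
    f <- em_fit(X, 2, code)
    for (S in f$sigma) expect_equal(S, diag(diag(S)), tolerance = 1e-10,
                                    label = paste(code, "diagonality"))
  }
  # VEV: shared shape (sorted eigenvalues proportional across components)
  f <- em_fit(X, 2, "VEV")
  e1 <- sort(eigen(f$sigma[[1]])$values); e2 <- sort(eigen(f$sigma[[2]])$values)
  expect_equal(e1 / vol(f$sigma[[1]]), e2 / vol(f$sigma[[2]]), tolerance = 1e-6)
})

test_that("VVV agrees with the independent mclust EM oracle under identical init", {
  skip_if_not_installed("mclust")
  # mclust::me() dispatches to exported helpers by bare name, so the package
  # must be attached, not just loaded
  if (!"package:mclust" %in% search()) {
    suppressMessages(library(mclust))
    withr::defer(try(detach("package:mclust"), silent = TRUE))
  }
  for (seed in 1:5) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(90, 0), ncol = 3),
               matrix(rnorm(90, 3), ncol = 3))
    z0 <- isozone:::ward_init(X, 2)
    ours <- em_fit(X, 2, "VVV", z0 = z0, tol = 1e-10)
    oracle <- mclust::me(X, modelName = "VVV", z = z0,
                         control = mclust::emControl(tol = c(1e-10, 1e-10),
                                                     itmax = c(10000, 10000)))
    expect_equal(ours$loglik, oracle$loglik, tolerance = 1e-6,
                 label = paste("VVV loglik, seed", seed))
  }
})

test_that("two-blob recovery: means, labels and ARI", {
  set.seed(12)
  X <- rbind(matrix(rnorm(600, 0, 1), ncol = 3),
             matrix(rnorm(600, 10, 1), ncol = 3))
  truth <- rep(1:2, each = 200)
  f <- em_fit(X, 2, "EII")
  mu_sorted <- f$mu[, order(f$mu[1, ])]
  expect_true(all(abs(mu_sorted[, 1] - 0) < 0.5))
  expect_true(all(abs(mu_sorted[, 2] - 10) < 0.5))
  lab <- classify(f)
  expect_gte(adjusted_rand_index(lab, truth), 0.95)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(lab, truth),
               mclust::adjustedRandIndex(lab, truth))
})

test_that("MAP classification breaks ties toward the lowest component", {
  f <- structure(list(z = rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0))),
                 class = "mixture_fit")
  expect_identical(classify(f), c(2L, 1L))
})

test_that("BIC surface and plateau selection follow the stated rules", {
  # tight single cloud: BIC penalty dominates, best k = 1 across codes
  set.seed(31)
  X1 <- matrix(rnorm(240, sd = 0.3), ncol = 3)
  surf1 <- fit_family(X1, k_range = 1:4, codes = c("EII", "VVI", "VVV"))
  expect_identical(best_fit(surf1)$k, 1L)

  # shape contract of the full family sweep
  set.seed(32)
  X2 <- make_blobs(40, seed = 32)$X
  surf <- suppressWarnings(fit_family(X2, k_range = 1:6))
  expect_identical(dim(surf$bic), c(6L, 10L))
  expect_identical(colnames(surf$bic), parameterizations())
  expect_identical(rownames(surf$bic), as.character(1:6))

  # hand-checkable plateau rule on a synthetic curve
  B <- matrix(c(-100, -50, -20, -19.5, -19.4), ncol = 1,
              dimnames = list(1:5, "VVV"))
  surf_h <- structure(list(bic = B,
                           fits = list(VVV = rep(list(NULL), 5)),
                           k_range = 1:5, codes = "VVV", n = 50, d = 3),
                      class = "bic_surface")
  expect_identical(select_model_plateau(surf_h, tau = 0.01)$k, 3L)

  # steeply rising curve: fallback to the argmax with a warning
  B2 <- matrix(c(-100, -60, -20), ncol = 1, dimnames = list(1:3, "VVV"))
  surf_r <- structure(list(bic = B2, fits = list(VVV = rep(list(NULL), 3)),
                           k_range = 1:3, codes = "VVV", n = 50, d = 3),
                      class = "bic_surface")
  expect_warning(sel <- select_model_plateau(surf_r, tau = 0.01), "plateau")
  expect_identical(sel$k, 3L)
})

test_that("BIC penalty ranks equal-likelihood models by parsimony", {
  # arithmetic consequence of the 2 ll - m log n convention, checked via
  # two codes with identical k=1 likelihood on diagonal-looking data
  set.seed(41)
  X <- matrix(rnorm(60), ncol = 3) %*% diag(c(1, 2, 3))
  f_eei <- em_fit(X, 1, "EEI")
  f_vvv <- em_fit(X, 1, "VVV")
  expect_gte(f_vvv$loglik, f_eei$loglik - 1e-9)
  if (abs(f_vvv$loglik - f_eei$loglik) < 1) {
    expect_gt(bic(f_eei) + (n_params("VVV", 1, 3) - n_params("EEI", 1, 3)) *
                log(nrow(X)), bic(f_vvv))
  }
})
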