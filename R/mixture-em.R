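#' Fit a Gaussian mixture with a constrained covariance structure by EM
#'
#' Expectation-maximization for a `k`-component multivariate normal mixture
#' under one of the ten covariance constraint patterns
#' (see [parameterizations()]). The E-step computes responsibilities
#' `z_ik` proportional to `pi_k phi(x_i; mu_k, Sigma_k)`; the M-step updates
#' weights, means and the decomposition parameters under the code's
#' constraints (closed forms where available, inner fixed-point iterations for
#' the volume/shape alternations). Iteration stops when the relative
#' log-likelihood change falls below `tol`.
#'
#' Initialization is deterministic: Ward-linkage agglomeration on (a seeded
#' subsample of at most `init_max_n` rows of) the data, cut at `k`, gives hard
#' initial assignments. Components whose covariance collapses (an eigenvalue
#' below `1e-8 * tr(S)/d`, `S` the pooled covariance) are regularized with a
#' warning.
#'
#' @param X Numeric matrix, `n x d` (rows are observations).
#' @param k Number of components (`n > k`).
#' @param code One of [parameterizations()].
#' @param z0 Optional `n x k` matrix of initial responsibilities; overrides
#'   the Ward initialization.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param init_max_n Subsample cap for the Ward initialization (default 2000).
#' @param init_seed Seed for the initialization subsample (only used when
#'   `n > init_max_n`); does not touch the global RNG stream.
#' @return An object of class `mixture_fit`: list with `code`, `k`, `d`, `n`,
#'   `pi`, `mu` (d x k), `sigma` (list of d x d), `z`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `n_regularized`.
#' @export
em_fit <- function(X, k, code, z0 = NULL, tol = 1e-8, max_iter = 1000,
                   init_max_n = 2000, init_seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  check_code(code)
  if (n <= k) stop("need more observations than components (n > k)", call. = FALSE)

  if (is.null(z0)) z0 <- ward_init(X, k, init_max_n, init_seed)
  z <- z0
  stopifnot(nrow(z) == n, ncol(z) == k)

  S_pooled <- stats::cov(X) * (n - 1) / n
  eig_floor <- 1e-8 * sum(diag(S_pooled)) / d
  eig_floor <- max(eig_floor, .Machine$double.xmin)

  loglik_trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  n_regularized <- 0L
  pi_k <- mu <- sigma <- NULL

  for (iter in seq_len(max_iter)) {
    # ---- M-step
    n_k <- colSums(z)
    if (any(n_k < 1e-10)) {
      # an emptied component: reseed it on the worst-fit point
      for (j in which(n_k < 1e-10)) {
        worst <- which.min(apply(z, 1, max))
        z[worst, ] <- 0; z[worst, j] <- 1
      }
      n_k <- colSums(z)
    }
    pi_k <- n_k / n
    mu <- vapply(seq_len(k), function(j) colSums(X * z[, j]) / n_k[j],
                 numeric(d))
    mu <- matrix(mu, nrow = d)
    W <- lapply(seq_len(k), function(j) {
      Xc <- sweep(X, 2, mu[, j])
      crossprod(Xc * sqrt(z[, j]))
    })
    sigma <- mstep_covariances(code, W, n_k, n, d)
    reg <- regularize_covariances(sigma, eig_floor)
    sigma <- reg$sigma
    n_regularized <- n_regularized + reg$n_fixed

    # ---- E-step
    logdens <- component_logdensity(X, mu, sigma)
    lw <- sweep(logdens, 2, log(pi_k), "+")
    mx <- lw[, 1]
    if (k > 1) for (j in 2:k) mx <- pmax(mx, lw[, j])
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    z <- exp(lw - lse)

    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(loglik) &&
        abs(ll - loglik) < tol * (abs(ll) + .Machine$double.eps)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  if (n_regularized > 0) {
    warning(sprintf("%s k=%d: %d covariance regularization(s) at the eigenvalue floor",
                    code, k, n_regularized), call. = FALSE)
  }
  # a component whose final covariance sits at the floor is a spurious
  # likelihood spike (unbounded-likelihood degeneracy); flag it so model
  # selection can ignore the fit (k = 1 on genuinely degenerate data is kept)
  degenerate <- k > 1 && any(vapply(sigma, function(S)
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <=
      eig_floor * 1.01, logical(1)))
  structure(list(code = code, k = k, d = d, n = n,
                 pi = pi_k, mu = mu, sigma = sigma, z = z,
                 loglik = loglik, loglik_trace = loglik_trace,
                 iterations = length(loglik_trace),
                 converged = converged,
                 n_regularized = n_regularized,
                 degenerate = degenerate),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %s, k=%d, d=%d, n=%d: loglik=%.4f (%s, %d iter)\n",
              x$code, x$k, x$d, x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

# log N(x; mu_j, Sigma_j) for every row and component, via Cholesky
component_logdensity <- function(X, mu, sigma) {
  n <- nrow(X); d <- ncol(X); k <- ncol(mu)
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    R <- chol(sigma[[j]])
    Xc <- sweep(X, 2, mu[, j])
    Q <- backsolve(R, t(Xc), transpose = TRUE)
    maha <- colSums(Q^2)
    out[, j] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + maha)
  }
  out
}

regularize_covariances <- function(sigma, floor) {
  n_fixed <- 0L
  sigma <- lapply(sigma, function(S) {
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values < floor)) {
      n_fixed <<- n_fixed + 1L
      v <- pmax(e$values, floor)
      S <- e$vectors %*% diag(v, nrow = nrow(S)) %*% t(e$vectors)
    }
    S
  })
  list(sigma = sigma, n_fixed = n_fixed)
}

# deterministic hard initialization: Ward agglomeration on a (seeded)
# subsample, remaining rows assigned to the nearest cluster centroid
ward_init <- function(X, k, init_max_n = 2000, init_seed = 1L) {
  n <- nrow(X)
  if (k == 1) return(matrix(1, n, 1))
  idx <- seq_len(n)
  if (n > init_max_n) {
    idx <- local_seed_sample(n, init_max_n, init_seed)
  }
  hc <- ward_tree(X[idx, , drop = FALSE])
  lab_sub <- stats::cutree(hc, k = k)
  centroids <- vapply(seq_len(k), function(j)
    colMeans(X[idx[lab_sub == j], , drop = FALSE]), numeric(ncol(X)))
  centroids <- matrix(centroids, nrow = ncol(X))
  d2 <- vapply(seq_len(k), function(j)
    rowSums(sweep(X, 2, centroids[, j])^2), numeric(n))
  lab <- max.col(-matrix(d2, nrow = n), ties.method = "first")
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), lab)] <- 1
  # guarantee no empty component
  for (j in seq_len(k)) {
    if (sum(z[, j]) == 0) {
      far <- which.max(d2[, j] * 0 + rowSums(d2))  # any row; rare fallback
      z[far, ] <- 0; z[far, j] <- 1
    }
  }
  z
}

ward_tree <- function(Xs) {
  stats::hclust(stats::dist(Xs), method = "ward.D2")
}

local_seed_sample <- function(n, size, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sort(sample.int(n, size))
}

#' Bayesian Information Criterion of a mixture fit
#'
#' `BIC = 2 * loglik - m * log(n)` with `m = n_params(code, k, d)`; larger is
#' better under this (maximization) convention. Non-converged fits yield `NA`.
#'
#' @param fit A [em_fit()] result.
#' @return Numeric scalar (or `NA` for a non-converged fit).
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) return(NA_real_)
  2 * fit$loglik - n_params(fit$code, fit$k, fit$d) * log(fit$n)
}

#' Maximum-a-posteriori component labels
#'
#' `argmax_k z_ik` per row; exact ties go to the lowest component index.
#'
#' @param fit A [em_fit()] result.
#' @return Integer vector of labels in `1..k`.
#' @export
classify <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  max.col(fit$z, ties.method = "first")
}
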