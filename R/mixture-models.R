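#' Covariance parameterization codes
#'
#' The ten constraint patterns on the eigen-decomposition
#' `Sigma_k = lambda_k D_k A_k D_k'` (lambda volume, A shape — a diagonal
#' matrix of determinant 1 — and D orientation). Each letter says whether
#' volume, shape and orientation are Equal across components, Variable, or
#' fixed to the Identity:
#' EII/VII spherical; EEI/VEI/EVI/VVI diagonal; EEE/EEV/VEV/VVV ellipsoidal.
#'
#' @return Character vector of the ten codes.
#' @export
parameterizations <- function() {
  c("EII", "VII", "EEI", "VEI", "EVI", "VVI", "EEE", "EEV", "VEV", "VVV")
}

check_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || !code %in% parameterizations()) {
    stop("unknown covariance parameterization: ", paste(code, collapse = ","),
         call. = FALSE)
  }
  code
}

#' Number of free parameters of a Gaussian mixture model
#'
#' `(k - 1)` mixing proportions, `k * d` means, plus the covariance parameters
#' implied by the constraint pattern (orientation contributes `d(d-1)/2` angles
#' per distinct orientation, shape `d - 1`, volume 1).
#'
#' @param code One of [parameterizations()].
#' @param k Number of components (>= 1).
#' @param d Data dimension (>= 1).
#' @return Integer parameter count.
#' @export
n_params <- function(code, k, d) {
  check_code(code)
  stopifnot(k >= 1, d >= 1)
  ori <- d * (d - 1) / 2   # orientation angles per distinct D
  shp <- d - 1             # shape parameters per distinct A
  cov_pars <- switch(code,
    EII = 1,
    VII = k,
    EEI = 1 + shp,
    VEI = k + shp,
    EVI = 1 + k * shp,
    VVI = k + k * shp,
    EEE = 1 + shp + ori,
    EEV = 1 + shp + k * ori,
    VEV = k + shp + k * ori,
    VVV = k * (1 + shp + ori)
  )
  as.integer((k - 1) + k * d + cov_pars)
}

# ---- constrained covariance M-steps -----------------------------------------
# Input: list of scatter matrices W_k = sum_i z_ik (x_i - mu_k)(x_i - mu_k)',
# component weights n_k, total n, dimension d. Output: list of Sigma_k.
# Closed forms where they exist; fixed-point iterations (to `tol` or
# `max_inner` sweeps) for the volume/shape alternations of VEI and VEV.

mstep_covariances <- function(code, W, n_k, n, d,
                              tol = 1e-10, max_inner = 200) {
  k <- length(W)
  Wsum <- Reduce(`+`, W)
  eye <- diag(d)
  rep_sigma <- function(S) rep(list(S), k)

  det_pos <- function(v) prod(pmax(v, .Machine$double.xmin))

  switch(code,
    EII = rep_sigma(eye * (sum(diag(Wsum)) / (n * d))),
    VII = lapply(seq_len(k), function(j)
      eye * (sum(diag(W[[j]])) / (n_k[j] * d))),
    EEI = rep_sigma(diag(pmax(diag(Wsum), 0) / n, nrow = d)),
    VVI = lapply(seq_len(k), function(j)
      diag(pmax(diag(W[[j]]), 0) / n_k[j], nrow = d)),
    VEI = {
      dW <- lapply(W, function(w) pmax(diag(w), 0))
      lambda <- vapply(seq_len(k), function(j) sum(dW[[j]]) / (n_k[j] * d),
                       numeric(1))
      B <- rep(1, d)
      for (it in seq_len(max_inner)) {
        Bnew <- Reduce(`+`, Map(function(w, l) w / l, dW, as.list(lambda)))
        Bnew <- Bnew / det_pos(Bnew)^(1 / d)
        lnew <- vapply(seq_len(k), function(j)
          sum(dW[[j]] / Bnew) / (n_k[j] * d), numeric(1))
        delta <- max(abs(Bnew - B), abs(lnew - lambda))
        B <- Bnew; lambda <- lnew
        if (delta < tol) break
      }
      lapply(seq_len(k), function(j) diag(lambda[j] * B, nrow = d))
    },
    EVI = {
      dW <- lapply(W, function(w) pmax(diag(w), .Machine$double.xmin))
      dets <- vapply(dW, function(v) det_pos(v)^(1 / d), numeric(1))
      lambda <- sum(dets) / n
      lapply(seq_len(k), function(j)
        diag(lambda * dW[[j]] / dets[j], nrow = d))
    },
    EEE = rep_sigma(Wsum / n),
    EEV = {
      eig <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
      Omega <- Reduce(`+`, lapply(eig, function(e) pmax(e$values, 0)))
      Lam <- Omega / n
      lapply(seq_len(k), function(j) {
        V <- eig[[j]]$vectors
        V %*% diag(Lam, nrow = d) %*% t(V)
      })
    },
    VEV = {
      eig <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
      Om <- lapply(eig, function(e) pmax(e$values, .Machine$double.xmin))
      lambda <- vapply(seq_len(k), function(j) sum(Om[[j]]) / (n_k[j] * d),
                       numeric(1))
      A <- rep(1, d)
      for (it in seq_len(max_inner)) {
        Anew <- Reduce(`+`, Map(function(o, l) o / l, Om, as.list(lambda)))
        Anew <- Anew / det_pos(Anew)^(1 / d)
        lnew <- vapply(seq_len(k), function(j)
          sum(Om[[j]] / Anew) / (n_k[j] * d), numeric(1))
        delta <- max(abs(Anew - A), abs(lnew - lambda))
        A <- Anew; lambda <- lnew
        if (delta < tol) break
      }
      lapply(seq_len(k), function(j) {
        V <- eig[[j]]$vectors
        V %*% diag(lambda[j] * A, nrow = d) %*% t(V)
      })
    },
    VVV = lapply(seq_len(k), function(j) W[[j]] / n_k[j])
  )
}
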