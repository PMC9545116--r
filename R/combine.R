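#' TE-weighted averaging of unwrapped multi-echo phase
#'
#' Combines the per-echo unwrapped phase into a total field as
#' `dB(r) = (1/gamma) sum_i w_i phi_i(r) / TE_i` with scalar weights
#' `w_i = TE_i / sum_j TE_j`, which collapses algebraically to
#' `(1/gamma) sum_i phi_i(r) / sum_j TE_j`. Longer echoes, whose phase has
#' the better SNR, therefore carry proportionally more weight. Any
#' TE-independent phase offset `phi0` is not modelled and biases the result
#' by `n * phi0 / (gamma * sum TE)`.
#'
#' @param unwrapped_phase_4d 4D array of per-echo unwrapped phase, radians.
#' @param echo_times_s Positive echo times, seconds.
#' @param mask Optional mask attached to the output.
#' @return A [field_map()] in Tesla with role `"total"`; the scalar weights
#'   are attached as attribute `"weights"` for audit.
#' @export
te_weighted_average <- function(unwrapped_phase_4d, echo_times_s,
                                mask = NULL) {
  tes <- echo_times_s
  if (any(tes <= 0)) stop("echo times must be positive")
  ne <- dim(unwrapped_phase_4d)[4]
  stopifnot(ne == length(tes))
  gam <- gyromagnetic_ratio()
  shape <- dim(unwrapped_phase_4d)[1:3]
  acc <- array(0, dim = shape)
  for (i in seq_len(ne)) acc <- acc + unwrapped_phase_4d[, , , i]
  fm <- field_map(acc / (gam * sum(tes)), "tesla", "total", mask)
  attr(fm, "weights") <- tes / sum(tes)
  fm
}

#' Voxel-wise R2* and M0 mapping from multi-echo magnitude
#'
#' Fits the mono-exponential decay `M(TE) = M0 exp(-R2* TE)` per voxel by
#' Gauss-Newton least squares on the magnitudes, initialised from the
#' closed-form ordinary least-squares line through `(TE, log M)`. R2* is
#' bounded to `[0, 2000]` s^-1 (stabilises low-signal venous voxels).
#'
#' @param magnitude_4d 4D non-negative magnitude array.
#' @param echo_times_s Echo times, seconds (>= 2).
#' @param mask Optional 3D logical array restricting the fit.
#' @param max_iter,tol Gauss-Newton controls.
#' @return List: `r2star` (3D, s^-1), `m0` (3D, a.u.), `excluded` (3D
#'   logical: voxels with non-positive magnitude at some echo inside the
#'   mask, where R2* is set to 0).
#' @export
fit_r2star <- function(magnitude_4d, echo_times_s, mask = NULL,
                       max_iter = 25, tol = 1e-8) {
  tes <- echo_times_s
  ne <- dim(magnitude_4d)[4]
  if (ne < 2) stop("at least 2 echoes required")
  stopifnot(ne == length(tes))
  shape <- dim(magnitude_4d)[1:3]
  mask <- as_mask(mask, shape)
  nvox <- prod(shape)
  M <- matrix(magnitude_4d, nvox, ne)
  ok <- as.vector(mask) & apply(M > 0, 1, all)

  r2 <- numeric(nvox)
  m0 <- numeric(nvox)
  if (any(ok)) {
    Mo <- M[ok, , drop = FALSE]
    y <- log(Mo)
    # closed-form OLS on (TE, log M)
    tbar <- mean(tes)
    ybar <- rowMeans(y)
    stt <- sum((tes - tbar)^2)
    slope <- as.vector((y - ybar) %*% (tes - tbar)) / stt
    r2o <- pmin(pmax(-slope, 0), 2000)
    m0o <- exp(ybar - slope * tbar)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(r2o, tes))        # nvox_ok x ne
      r <- Mo - m0o * E                 # residual
      # J columns: dM/dM0 = E ; dM/dR2* = -M0 TE E
      a11 <- rowSums(E^2)
      a12 <- -m0o * as.vector((E^2) %*% tes)
      a22 <- m0o^2 * as.vector((E^2) %*% tes^2)
      g1 <- rowSums(E * r)
      g2 <- -m0o * rowSums(E * r * rep(tes, each = nrow(E)))
      det <- a11 * a22 - a12^2
      det[abs(det) < 1e-300] <- 1
      dm0 <- (a22 * g1 - a12 * g2) / det
      dr2 <- (a11 * g2 - a12 * g1) / det
      m0o <- pmax(m0o + dm0, 0)
      r2o <- pmin(pmax(r2o + dr2, 0), 2000)
      if (max(abs(dr2) / pmax(r2o, 1), abs(dm0) / pmax(m0o, 1e-12)) < tol)
        break
    }
    r2[ok] <- r2o
    m0[ok] <- m0o
  }
  list(r2star = array(r2, dim = shape), m0 = array(m0, dim = shape),
       excluded = array(as.vector(mask) & !ok, dim = shape))
}

#' SNR-weighted averaging of background-free multi-echo phase
#'
#' Combines per-echo local (unwrapped, background-free) phase into a local
#' field as `dB(r) = (1/gamma) sum_i w_i(r) phi_i(r) / TE_i` with
#' voxel-wise weights
#' `w_i(r) = TE_i exp(-TE_i R2*(r)) / sum_j TE_j exp(-TE_j R2*(r))`,
#' which track the TE of optimal phase SNR in each tissue. At `R2* = 0`
#' the weights reduce exactly to the TE weights.
#'
#' @param local_phase_4d 4D per-echo local phase, radians
#'   (SHARP-processed).
#' @param echo_times_s Positive echo times, seconds.
#' @param r2star 3D non-negative R2* map, s^-1.
#' @param mask Optional mask attached to the output.
#' @return A [field_map()] in Tesla with role `"local"`; voxel-wise weights
#'   are attached as attribute `"weights"` (4D array).
#' @export
snr_weighted_average <- function(local_phase_4d, echo_times_s, r2star,
                                 mask = NULL) {
  tes <- echo_times_s
  if (any(tes <= 0)) stop("echo times must be positive")
  if (any(r2star < 0)) stop("r2star must be non-negative")
  ne <- dim(local_phase_4d)[4]
  stopifnot(ne == length(tes))
  gam <- gyromagnetic_ratio()
  shape <- dim(local_phase_4d)[1:3]
  wsum <- array(0, dim = shape)
  wts <- array(0, dim = c(shape, ne))
  for (i in seq_len(ne)) {
    wts[, , , i] <- tes[i] * exp(-tes[i] * r2star)
    wsum <- wsum + wts[, , , i]
  }
  acc <- array(0, dim = shape)
  for (i in seq_len(ne)) {
    wts[, , , i] <- wts[, , , i] / wsum
    acc <- acc + wts[, , , i] * local_phase_4d[, , , i] / tes[i]
  }
  fm <- field_map(acc / gam, "tesla", "local", mask)
  attr(fm, "weights") <- wts
  fm
}

#' Magnitude-weighted averaging of per-echo susceptibility maps
#'
#' Combines TE-dependent susceptibility maps (one inversion per echo) as
#' `chi(r) = sum_i w_i(r) chi_i(r)` with voxel-wise weights
#' `w_i(r) = M(r,TE_i)^2 TE_i^2 / sum_j M(r,TE_j)^2 TE_j^2`, the inverse
#' phase-noise-variance weighting implied by the reciprocal relation
#' between phase noise and magnitude SNR.
#'
#' @param chi_per_echo_4d 4D array of per-echo susceptibility maps, ppm.
#' @param magnitude_4d 4D magnitude array (same shape).
#' @param echo_times_s Positive echo times, seconds.
#' @param mask Optional mask attached to the output.
#' @return List: `chi` (3D, ppm), `weights` (4D), `undefined` (3D logical:
#'   voxels with zero magnitude at every echo, set to 0).
#' @export
susceptibility_weighted_average <- function(chi_per_echo_4d, magnitude_4d,
                                            echo_times_s, mask = NULL) {
  tes <- echo_times_s
  if (any(tes <= 0)) stop("echo times must be positive")
  ne <- dim(chi_per_echo_4d)[4]
  stopifnot(identical(dim(chi_per_echo_4d), dim(magnitude_4d)),
            ne == length(tes))
  shape <- dim(chi_per_echo_4d)[1:3]
  wts <- array(0, dim = c(shape, ne))
  wsum <- array(0, dim = shape)
  for (i in seq_len(ne)) {
    wts[, , , i] <- magnitude_4d[, , , i]^2 * tes[i]^2
    wsum <- wsum + wts[, , , i]
  }
  undef <- wsum == 0
  wsum[undef] <- 1
  chi <- array(0, dim = shape)
  for (i in seq_len(ne)) {
    wts[, , , i] <- wts[, , , i] / wsum
    chi <- chi + wts[, , , i] * chi_per_echo_4d[, , , i]
  }
  chi[undef] <- 0
  for (i in seq_len(ne)) {
    wslice <- wts[, , , i]
    wslice[undef] <- 0
    wts[, , , i] <- wslice
  }
  list(chi = chi, weights = wts, undefined = undef)
}
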