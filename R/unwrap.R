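#' Temporal phase unwrapping across echoes
#'
#' Voxel-wise: the first echo is left unchanged and each later echo is
#' shifted by the integer multiple of 2*pi that brings every successive
#' increment into `(-pi, pi]`. Valid whenever the true phase evolution per
#' echo spacing stays below pi.
#'
#' @param phase_4d 4D phase array (x, y, z, echo), radians.
#' @param echo_times_s Echo times (only the count is used).
#' @return 4D array of temporally unwrapped phase.
#' @export
temporal_unwrap <- function(phase_4d, echo_times_s) {
  ne <- dim(phase_4d)[4]
  if (!is.null(echo_times_s) && length(echo_times_s) != ne)
    stop("echo count mismatch")
  if (ne < 2) {
    warning("single echo: temporal unwrapping is the identity")
    return(phase_4d)
  }
  out <- phase_4d
  prev <- phase_4d[, , , 1, drop = FALSE]
  acc <- prev
  for (i in 2:ne) {
    cur <- phase_4d[, , , i, drop = FALSE]
    inc <- wrap_phase(cur - prev)
    acc <- acc + inc
    out[, , , i] <- acc
    prev <- cur
  }
  out
}

#' Laplacian phase unwrapping
#'
#' Computes the Laplacian of the wrapped phase through the identity
#' `lap(phi) = cos(phi_w) lap(sin phi_w) - sin(phi_w) lap(cos phi_w)` with an
#' FFT-diagonalised 7-point discrete Laplacian (periodic boundary), then
#' applies the truncated inverse Laplacian: k-space components whose
#' eigenvalue magnitude is at or below `tsvd_threshold` are zeroed rather
#' than inverted (the stencil eigenvalues span the fixed range `[-12, 0]`,
#' so the threshold is compared against them directly; at the default
#' 1e-10 only the DC component is truncated). The output is set to zero
#' mean over the mask (the truncated null space makes the mean
#' unobservable).
#'
#' Because the inverse operator is regularised, low-spatial-frequency
#' content (including part of any background field) is attenuated; this
#' high-pass character is intrinsic to Laplacian-based unwrapping.
#'
#' @param phase_3d 3D wrapped phase, radians.
#' @param mask Optional 3D logical array; defines the mean-zero reference.
#' @param tsvd_threshold Relative truncation threshold (default 1e-10).
#' @return 3D unwrapped phase, radians, mean-zero over the mask.
#' @export
laplacian_unwrap <- function(phase_3d, mask = NULL, tsvd_threshold = 1e-10) {
  if (!all(is.finite(phase_3d))) stop("phase must be finite")
  if (tsvd_threshold >= 1)
    stop("tsvd_threshold >= 1 truncates far beyond the null space")
  mask <- as_mask(mask, dim(phase_3d))
  L <- laplacian_eigenvalues(dim(phase_3d))
  lap <- cos(phase_3d) * Re(ifft3(L * fft3(sin(phase_3d)))) -
    sin(phase_3d) * Re(ifft3(L * fft3(cos(phase_3d))))
  keep <- abs(L) > tsvd_threshold
  inv <- ifelse(keep, 1 / L, 0)
  out <- Re(ifft3(inv * fft3(lap)))
  out - mean(out[mask])
}
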