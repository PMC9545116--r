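#' SHARP background-field removal
#'
#' Sophisticated harmonic artifact reduction for phase data: exploits the
#' harmonicity of background fields inside the brain (their Laplacian
#' vanishes there, because their sources lie outside) to separate the local,
#' tissue-induced field. The forward step applies the minimum-size 3-voxel
#' isotropic discrete Laplacian through the trigonometric identity
#' `cos(x) lap(sin x) - sin(x) lap(cos x)`, so wrapped phase is admissible
#' and the operation performs simultaneous spatial unwrapping and background
#' removal; the result is restricted to the mask eroded by `erode_voxels`
#' and then deconvolved by truncated inversion of the kernel's k-space
#' transform: components whose eigenvalue magnitude is at or below
#' `tsvd_threshold` are zeroed. The threshold is compared against the
#' stencil eigenvalues themselves (fixed range `[-12, 0]`, so the value is
#' scale-free for this kernel); at the default 0.05 the truncated set spans
#' spatial wavelengths longer than about 28 voxels, which removes the
#' smooth background remnants while preserving anatomical-scale local
#' fields. The output is mean-zero over the eroded mask.
#'
#' The operation is linear for smooth unwrapped inputs, so it can equally be
#' applied to a combined field map in Tesla (the trigonometric identity
#' reduces to the plain Laplacian at small arguments).
#'
#' @param phase_like 3D array: wrapped/unwrapped phase in radians, or a
#'   field in Tesla.
#' @param mask 3D logical brain mask; must survive the erosion.
#' @param kernel Deconvolution kernel; only `"laplacian3"` (the 3x3x3
#'   7-point Laplacian) is implemented.
#' @param tsvd_threshold Relative truncation threshold (default 0.05).
#' @param erode_voxels Mask erosion radius in voxels (default 5).
#' @return List: `values` (3D local field/phase, zero outside the eroded
#'   mask, mean-zero inside), `eroded_mask`.
#' @export
sharp <- function(phase_like, mask, kernel = "laplacian3",
                  tsvd_threshold = 0.05, erode_voxels = 5) {
  if (!all(is.finite(phase_like))) stop("input must be finite")
  if (!identical(kernel, "laplacian3"))
    stop("only the 'laplacian3' kernel is implemented")
  if (tsvd_threshold >= 1)
    stop("tsvd_threshold >= 1 truncates the whole spectrum")
  mask <- as_mask(mask, dim(phase_like))
  m_e <- erode_mask(mask, erode_voxels)
  if (!any(m_e)) stop("eroded mask is empty")
  L <- laplacian_eigenvalues(dim(phase_like))
  lap <- cos(phase_like) * Re(ifft3(L * fft3(sin(phase_like)))) -
    sin(phase_like) * Re(ifft3(L * fft3(cos(phase_like))))
  lap[!m_e] <- 0
  keep <- abs(L) > tsvd_threshold
  inv <- ifelse(keep, 1 / L, 0)
  out <- Re(ifft3(inv * fft3(lap)))
  out[!m_e] <- 0
  out[m_e] <- out[m_e] - mean(out[m_e])
  list(values = out, eroded_mask = m_e)
}
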