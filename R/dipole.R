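#' Magnetic dipole kernel in k-space
#'
#' Builds `D(k) = 1/3 - (k . b)^2 / |k|^2` on the FFT grid of the stated
#' shape, with the DC component set to zero and frequencies per axis scaled
#' by the reciprocal voxel size. This is the unit-field kernel relating a
#' susceptibility distribution (ppm) to the field perturbation it induces
#' (ppm of B0): `field = IFFT[D * FFT(chi)]`. Its zero cone at the magic
#' angle makes the field-to-chi inversion ill-posed.
#'
#' @param shape Length-3 integer grid size.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param b0_direction Unit 3-vector along the main field.
#' @param alpha Optional Tikhonov regularisation parameter stored with the
#'   kernel for use by the noise-propagation routines.
#' @return Object of class `dipole_kernel`: list with `d_k` (3D array in
#'   `[-2/3, 1/3]`), grid metadata, and `alpha`.
#' @export
dipole_kernel <- function(shape, voxel_size_mm = c(1, 1, 1),
                          b0_direction = c(0, 0, 1), alpha = NA_real_) {
  b <- check_unit_vector(b0_direction)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0))
  kx <- fft_index(shape[1]) / (shape[1] * voxel_size_mm[1])
  ky <- fft_index(shape[2]) / (shape[2] * voxel_size_mm[2])
  kz <- fft_index(shape[3]) / (shape[3] * voxel_size_mm[3])
  KX <- array(kx, dim = shape)
  KY <- array(rep(ky, each = shape[1]), dim = shape)
  KZ <- array(rep(kz, each = shape[1] * shape[2]), dim = shape)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b[1] + KY * b[2] + KZ * b[3]
  d <- 1 / 3 - kb^2 / k2
  d[1, 1, 1] <- 0 # DC convention: the mean field offset is unobservable
  structure(list(d_k = d, shape = shape, voxel_size_mm = voxel_size_mm,
                 b0_direction = b, alpha = alpha),
            class = "dipole_kernel")
}

#' @export
print.dipole_kernel <- function(x, ...) {
  cat("<dipole_kernel> ", paste(x$shape, collapse = "x"),
      " b0=(", paste(round(x$b0_direction, 3), collapse = ","),
      ") alpha=", format(x$alpha), "\n", sep = "")
  invisible(x)
}

# Forward dipole convolution: chi (ppm) -> field (Tesla).
dipole_forward <- function(chi_ppm, kernel, b0_tesla) {
  f_ppm <- Re(ifft3(kernel$d_k * fft3(chi_ppm)))
  ppm_to_field(f_ppm, b0_tesla)
}
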