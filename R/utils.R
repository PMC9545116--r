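#' Proton gyromagnetic ratio
#'
#' Angular gyromagnetic ratio of the proton, `2*pi*42.577478518e6` rad s^-1 T^-1.
#' All field maps in this package are carried in Tesla and converted to ppm of
#' B0 only where stated.
#'
#' @return Scalar, rad s^-1 T^-1.
#' @export
gyromagnetic_ratio <- function() 2 * pi * 42.577478518e6

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
fft3 <- function(x) stats::fft(x)

#' @keywords internal
#' @noRd
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Integer FFT frequency index per axis, DC at the first element (corner).
fft_index <- function(n) {
  i <- 0L:(n - 1L)
  i[i > n / 2] <- i[i > n / 2] - n
  i
}

# Eigenvalues of the 7-point discrete Laplacian (center -6, six face
# neighbours +1) diagonalised by the FFT with periodic boundaries, in voxel
# units. Range [-12, 0]; zero only at DC.
laplacian_eigenvalues <- function(shape) {
  lx <- 2 * (cos(2 * pi * fft_index(shape[1]) / shape[1]) - 1)
  ly <- 2 * (cos(2 * pi * fft_index(shape[2]) / shape[2]) - 1)
  lz <- 2 * (cos(2 * pi * fft_index(shape[3]) / shape[3]) - 1)
  outer(outer(lx, ly, `+`), lz, `+`)
}

# Wrap values into (-pi, pi].
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

as_mask <- function(mask, shape) {
  if (is.null(mask)) return(array(TRUE, dim = shape))
  m <- mask != 0
  if (!identical(dim(m), as.integer(shape)) && !identical(dim(m), shape))
    stopifnot(all(dim(m) == shape))
  m
}

# Deterministic sub-stream seed derived from a master seed; kept below 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 7919 + as.double(offset) * 104729) %% 2147483647)
}

check_unit_vector <- function(v, name = "b0_direction") {
  if (length(v) != 3 || !all(is.finite(v)))
    stop(name, " must be a finite 3-vector")
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(name, " must be non-zero")
  if (abs(n - 1) > 1e-6)
    stop(name, " must be a unit vector (norm ", format(n), ")")
  v / n
}

# Shift an array along one axis by `by` voxels, filling vacated entries.
shift_array <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, dim = d))
  idx_src <- lapply(d, seq_len)
  idx_dst <- lapply(d, seq_len)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1L):n
    idx_src[[axis]] <- 1L:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1L:(n + by)
    idx_src[[axis]] <- (1L - by):n
  }
  out <- array(fill, dim = d)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Convert a field map in Tesla to ppm of B0
#'
#' @param field 3D array in Tesla.
#' @param b0_tesla Main field strength in Tesla.
#' @return 3D array in ppm.
#' @export
field_to_ppm <- function(field, b0_tesla) field / (b0_tesla * 1e-6)

#' @rdname field_to_ppm
#' @param ppm 3D array in ppm of B0.
#' @export
ppm_to_field <- function(ppm, b0_tesla) ppm * b0_tesla * 1e-6
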