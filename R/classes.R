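#' Field map container
#'
#' A 3D field-perturbation volume with a units tag, a role tag and a mask.
#' Roles follow the field decomposition `total = background + local`: the
#' total field contains both harmonic background contributions (exterior
#' sources) and the local, tissue-induced part that carries the
#' susceptibility information.
#'
#' @param values 3D numeric array.
#' @param units One of `"tesla"`, `"radians"` (phase at a given TE), `"ppm"`.
#' @param role One of `"total"`, `"background"`, `"local"`.
#' @param mask 3D logical array (or NULL for the whole grid).
#' @param te_s Echo time in seconds, required when `units = "radians"`.
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, units = c("tesla", "radians", "ppm"),
                      role = c("total", "background", "local"),
                      mask = NULL, te_s = NULL) {
  units <- match.arg(units)
  role <- match.arg(role)
  stopifnot(length(dim(values)) == 3)
  mask <- as_mask(mask, dim(values))
  if (!all(is.finite(values[mask]))) stop("field map not finite inside mask")
  structure(list(values = values, units = units, role = role,
                 mask = mask, te_s = te_s),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map> ", paste(dim(x$values), collapse = "x"),
      " role=", x$role, " units=", x$units,
      " mask voxels=", sum(x$mask), "\n", sep = "")
  invisible(x)
}

# Accept either a field_map or a bare array known to be in Tesla.
field_values_tesla <- function(x, b0_tesla = NULL) {
  if (inherits(x, "field_map")) {
    switch(x$units,
      tesla = x$values,
      ppm = {
        if (is.null(b0_tesla)) stop("b0_tesla needed to convert ppm field")
        ppm_to_field(x$values, b0_tesla)
      },
      radians = {
        if (is.null(x$te_s)) stop("radians field map lacks te_s")
        x$values / (gyromagnetic_ratio() * x$te_s)
      })
  } else x
}

field_mask <- function(x, default_shape = NULL) {
  if (inherits(x, "field_map")) x$mask else as_mask(NULL, default_shape)
}

#' Susceptibility map container
#'
#' @param chi 3D array in ppm, zero outside `mask`.
#' @param mask 3D logical array.
#' @param b0_tesla Field strength the map refers to.
#' @param alpha_used Tikhonov regularisation parameter used in the inversion.
#' @param correction_factor Underestimation-correction scale applied.
#' @return An object of class `chi_map`.
#' @export
chi_map <- function(chi, mask, b0_tesla, alpha_used = NA_real_,
                    correction_factor = 1) {
  mask <- as_mask(mask, dim(chi))
  if (!all(is.finite(chi[mask]))) stop("chi not finite inside mask")
  chi[!mask] <- 0
  structure(list(chi = chi, mask = mask, b0_tesla = b0_tesla,
                 alpha_used = alpha_used,
                 correction_factor = correction_factor),
            class = "chi_map")
}

#' @export
print.chi_map <- function(x, ...) {
  cat("<chi_map> ", paste(dim(x$chi), collapse = "x"),
      " alpha=", format(x$alpha_used, digits = 3),
      " correction=", format(x$correction_factor, digits = 4),
      " mean|chi| in mask=", format(mean(abs(x$chi[x$mask])), digits = 3),
      " ppm\n", sep = "")
  invisible(x)
}

#' Multi-echo GRE acquisition container
#'
#' Holds a 4D magnitude and a 4D phase volume (echo along the 4th axis),
#' the echo-time list and the field metadata of a gradient-recalled-echo
#' acquisition.
#'
#' @param magnitude 4D non-negative array (x, y, z, echo).
#' @param phase 4D array of phase in radians, each value in `(-pi, pi]`.
#' @param echo_times_s Strictly increasing vector of echo times in seconds.
#' @param voxel_size_mm Length-3 voxel size.
#' @param b0_tesla Field strength in Tesla.
#' @param b0_direction Unit 3-vector of the main field direction.
#' @return An object of class `multi_echo_gre`.
#' @export
multi_echo_gre <- function(magnitude, phase, echo_times_s,
                           voxel_size_mm = c(1, 1, 1), b0_tesla = 3,
                           b0_direction = c(0, 0, 1)) {
  stopifnot(length(dim(magnitude)) == 4, identical(dim(magnitude), dim(phase)))
  if (dim(magnitude)[4] != length(echo_times_s))
    stop("4th-axis length must equal the number of echo times")
  if (length(echo_times_s) >= 2 && any(diff(echo_times_s) <= 0))
    stop("echo times must be strictly increasing")
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  if (any(phase > pi | phase <= -pi))
    stop("phase must lie in (-pi, pi]")
  structure(list(magnitude = magnitude, phase = phase,
                 echo_times_s = as.numeric(echo_times_s),
                 voxel_size_mm = voxel_size_mm, b0_tesla = b0_tesla,
                 b0_direction = check_unit_vector(b0_direction)),
            class = "multi_echo_gre")
}

#' @export
print.multi_echo_gre <- function(x, ...) {
  cat("<multi_echo_gre> ", paste(dim(x$magnitude), collapse = "x"),
      " TEs(ms)=", paste(round(x$echo_times_s * 1e3, 2), collapse = ","),
      " B0=", x$b0_tesla, "T\n", sep = "")
  invisible(x)
}
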