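#' Default tissue table for the digital head phantom
#'
#' Regional susceptibility (ppm, referenced to surrounding tissue), proton
#' density M0 (arbitrary units, GM-normalised) and T2* (ms) with per-voxel
#' SDs. Values are configuration defaults chosen within literature ranges
#' for 3 T brain tissue; a user-supplied table (same columns) reproduces any
#' other parameterisation.
#'
#' @return A tibble with columns `region`, `chi_mean_ppm`, `chi_sd_ppm`,
#'   `m0_mean`, `m0_sd`, `t2star_mean_ms`, `t2star_sd_ms`.
#' @export
default_tissue_table <- function() {
  tibble::tibble(
    region = c("GM", "WM", "CSF", "CN", "PU", "GP", "TH", "vein"),
    chi_mean_ppm = c(0.02, -0.03, 0.00, 0.06, 0.09, 0.18, 0.02, 0.45),
    chi_sd_ppm = c(0.010, 0.010, 0.005, 0.015, 0.015, 0.020, 0.010, 0.030),
    m0_mean = c(1.00, 0.80, 1.00, 0.95, 0.95, 0.85, 0.95, 0.85),
    m0_sd = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    t2star_mean_ms = c(60, 55, 500, 55, 50, 35, 60, 20),
    t2star_sd_ms = c(5, 5, 50, 5, 5, 5, 5, 3)
  )
}

# Default region geometries in grid-relative coordinates: centers as
# fractions of each grid dimension, lengths as fractions of the smallest
# dimension. Later regions overwrite earlier ones where they overlap; the
# venous arc (a superior-sagittal-sinus analogue bent in the sagittal plane)
# is kept at radius 0.24 so it survives 5-voxel mask erosion at desk-scale
# grid sizes.
default_region_list <- function() {
  ell <- function(region, center, semi_axes)
    list(region = region, type = "ellipsoid", center = center,
         semi_axes = semi_axes)
  list(
    ell("GM", c(0.50, 0.50, 0.50), c(0.40, 0.45, 0.38)),
    ell("WM", c(0.50, 0.50, 0.50), c(0.30, 0.34, 0.27)),
    ell("CSF", c(0.43, 0.52, 0.52), c(0.045, 0.110, 0.050)),
    ell("CSF", c(0.57, 0.52, 0.52), c(0.045, 0.110, 0.050)),
    ell("CN", c(0.40, 0.60, 0.55), c(0.035, 0.060, 0.050)),
    ell("CN", c(0.60, 0.60, 0.55), c(0.035, 0.060, 0.050)),
    ell("PU", c(0.34, 0.53, 0.52), c(0.040, 0.070, 0.050)),
    ell("PU", c(0.66, 0.53, 0.52), c(0.040, 0.070, 0.050)),
    ell("GP", c(0.39, 0.51, 0.50), c(0.030, 0.050, 0.040)),
    ell("GP", c(0.61, 0.51, 0.50), c(0.030, 0.050, 0.040)),
    ell("TH", c(0.44, 0.42, 0.50), c(0.045, 0.070, 0.050)),
    ell("TH", c(0.56, 0.42, 0.50), c(0.045, 0.070, 0.050)),
    list(region = "vein", type = "cylinder_arc",
         center = c(0.50, 0.50, 0.50), axis = 1L, radius = 0.24,
         tube_radius = 0.022, angle_deg = c(30, 180))
  )
}

#' Specification of a synthetic multi-echo GRE head phantom
#'
#' Collects the geometry, tissue properties, acquisition and noise settings
#' from which ground-truth maps and noisy multi-echo complex data are
#' generated. Defaults emulate a 3 T five-echo protocol (first echo 3 ms,
#' echo spacing 5.4 ms) with complex Gaussian noise of SD 0.07 added
#' independently to the real and imaginary channels.
#'
#' @param grid_shape Length-3 positive integers.
#' @param voxel_size_mm Length-3 positive voxel size.
#' @param b0_tesla Field strength (default 3).
#' @param b0_direction Unit 3-vector (default along the 3rd axis).
#' @param regions Ordered list of region geometries (see
#'   [default_region_list()]); later regions overwrite earlier labels.
#' @param tissue_table Tissue property table, see [default_tissue_table()].
#' @param phi0_model Either `"none"` or a numeric vector of polynomial
#'   coefficients `c(a0, ax, ay, az)` defining a smooth phase offset
#'   `a0 + ax*u + ay*v + az*w` in grid-normalised coordinates `u,v,w` in
#'   `[-1, 1]`.
#' @param noise_sd Complex channel noise SD (default 0.07).
#' @param echo_times_s Increasing echo times (default 5 echoes, 3 ms first
#'   echo, 5.4 ms spacing).
#' @param air_chi_ppm Susceptibility assigned outside the head (default 0:
#'   the phantom is self-referenced with tissue values as offsets; set to
#'   about 9 ppm to emulate strong air-tissue background fields).
#' @param seed Master integer seed; property sampling and each (echo,
#'   repeat) noise draw use deterministic sub-streams.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_size_mm = c(1, 1, 1),
                         b0_tesla = 3,
                         b0_direction = c(0, 0, 1),
                         regions = default_region_list(),
                         tissue_table = default_tissue_table(),
                         phi0_model = "none",
                         noise_sd = 0.07,
                         echo_times_s = 0.003 + 0.0054 * (0:4),
                         air_chi_ppm = 0,
                         seed = 20220629) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            all(voxel_size_mm > 0), b0_tesla > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(echo_times_s) < 1 ||
      (length(echo_times_s) > 1 && any(diff(echo_times_s) <= 0)))
    stop("echo_times_s must be strictly increasing, length >= 1")
  if (any(echo_times_s <= 0)) stop("echo times must be positive")
  tt <- tissue_table
  need <- c("region", "chi_mean_ppm", "chi_sd_ppm", "m0_mean", "m0_sd",
            "t2star_mean_ms", "t2star_sd_ms")
  if (!all(need %in% names(tt))) stop("tissue_table lacks required columns")
  if (any(tt$t2star_mean_ms <= 0)) stop("all t2star_mean_ms must be > 0")
  if (any(tt$m0_mean < 0)) stop("all m0_mean must be >= 0")
  miss <- setdiff(vapply(regions, `[[`, "", "region"), tt$region)
  if (length(miss))
    stop("regions missing from tissue_table: ", paste(miss, collapse = ", "))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 b0_tesla = b0_tesla,
                 b0_direction = check_unit_vector(b0_direction),
                 regions = regions, tissue_table = tt,
                 phi0_model = phi0_model, noise_sd = noise_sd,
                 echo_times_s = as.numeric(echo_times_s),
                 air_chi_ppm = air_chi_ppm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$grid_shape, collapse = "x"),
      ", ", length(x$regions), " regions, ", length(x$echo_times_s),
      " echoes, noise_sd=", x$noise_sd, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Realise one geometry primitive as a logical volume.
region_voxels <- function(geom, shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  smin <- min(shape)
  X <- array(seq_len(nx), dim = shape)
  Y <- array(rep(seq_len(ny), each = nx), dim = shape)
  Z <- array(rep(seq_len(nz), each = nx * ny), dim = shape)
  ctr <- geom$center * shape
  if (geom$type == "ellipsoid") {
    ax <- geom$semi_axes * smin
    ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
      ((Z - ctr[3]) / ax[3])^2 <= 1
  } else if (geom$type == "box") {
    hw <- geom$half_width * smin
    abs(X - ctr[1]) <= hw[1] & abs(Y - ctr[2]) <= hw[2] &
      abs(Z - ctr[3]) <= hw[3]
  } else if (geom$type == "cylinder_arc") {
    ax <- geom$axis
    plane <- setdiff(1:3, ax)
    coords <- list(X, Y, Z)
    u <- coords[[plane[1]]] - ctr[plane[1]]
    v <- coords[[plane[2]]] - ctr[plane[2]]
    w <- coords[[ax]] - ctr[ax]
    R <- geom$radius * smin
    rt <- max(geom$tube_radius * smin, 1.2) # never thinner than one voxel
    rad <- sqrt(u^2 + v^2)
    ang <- atan2(v, u) * 180 / pi
    ang[ang < 0] <- ang[ang < 0] + 360
    inarc <- ang >= geom$angle_deg[1] & ang <= geom$angle_deg[2]
    (rad - R)^2 + w^2 <= rt^2 & inarc
  } else stop("unknown geometry type: ", geom$type)
}

# Per-voxel Gaussian property sampling; one stream per property so the label
# geometry does not perturb the draws of other properties.
sample_property <- function(labels, region_names, means, sds, seed,
                            clip_min = -Inf) {
  out <- array(0, dim = dim(labels))
  z <- withr::with_seed(seed, stats::rnorm(length(labels)))
  for (i in seq_along(region_names)) {
    sel <- labels == i
    if (!any(sel)) next
    out[sel] <- means[i] + sds[i] * z[sel]
  }
  pmax(out, clip_min)
}

#' Build the ground-truth property maps of a phantom
#'
#' Paints the region list onto the grid (later regions overwrite earlier
#' labels), draws voxel-wise susceptibility, M0 and T2* values as
#' `mean + SD * z` with independent standard-normal `z` (seeded sub-stream),
#' and evaluates the phase-offset model. The brain mask is the union of all
#' region geometries; the background (air) gets `air_chi_ppm`, M0 = 0 and
#' T2* clipped at 1 ms is enforced everywhere so the signal model stays
#' valid.
#'
#' @param spec A [phantom_spec()].
#' @return List with `labels` (integer array), `name_map` (label index to
#'   region name), `brain_mask`, `chi_true` (ppm), `m0_true`, `t2star_true`
#'   (ms), `phi0_true` (radians), and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  labels <- array(0L, dim = shape)
  region_names <- vapply(spec$regions, `[[`, "", "region")
  for (i in seq_along(spec$regions)) {
    vox <- region_voxels(spec$regions[[i]], shape)
    if (!any(vox))
      stop("region ", region_names[i], " lies outside the grid")
    labels[vox] <- i
  }
  brain_mask <- labels > 0L
  tt <- spec$tissue_table
  ridx <- match(region_names, tt$region)
  chi <- sample_property(labels, region_names,
                         tt$chi_mean_ppm[ridx], tt$chi_sd_ppm[ridx],
                         derive_seed(spec$seed, 1))
  chi[!brain_mask] <- spec$air_chi_ppm
  m0 <- sample_property(labels, region_names,
                        tt$m0_mean[ridx], tt$m0_sd[ridx],
                        derive_seed(spec$seed, 2), clip_min = 0)
  m0[!brain_mask] <- 0
  t2s <- sample_property(labels, region_names,
                         tt$t2star_mean_ms[ridx], tt$t2star_sd_ms[ridx],
                         derive_seed(spec$seed, 3), clip_min = 1)
  t2s[!brain_mask] <- 1 # irrelevant where m0 = 0, but keeps the model valid
  phi0 <- phi0_map(spec)
  list(labels = labels, name_map = region_names, brain_mask = brain_mask,
       chi_true = chi, m0_true = m0, t2star_true = t2s, phi0_true = phi0,
       spec = spec)
}

phi0_map <- function(spec) {
  shape <- spec$grid_shape
  if (identical(spec$phi0_model, "none")) return(array(0, dim = shape))
  cf <- spec$phi0_model
  stopifnot(is.numeric(cf), length(cf) == 4)
  u <- array(2 * (seq_len(shape[1]) - 0.5) / shape[1] - 1, dim = shape)
  v <- array(rep(2 * (seq_len(shape[2]) - 0.5) / shape[2] - 1,
                 each = shape[1]), dim = shape)
  w <- array(rep(2 * (seq_len(shape[3]) - 0.5) / shape[3] - 1,
                 each = shape[1] * shape[2]), dim = shape)
  cf[1] + cf[2] * u + cf[3] * v + cf[4] * w
}

#' Simulate total, background and local fields from a susceptibility map
#'
#' The total field is the dipole convolution of the full susceptibility
#' distribution, `B0 * 1e-6 * IFFT[D(k) FFT(chi)]` (Tesla). The ground-truth
#' local field follows the reference-scan decomposition: it is the field
#' re-simulated from the source distribution with everything outside the
#' brain mask removed and the mask-mean susceptibility subtracted inside,
#' so that the background field (total minus local) contains only exterior
#' and mean-offset sources, which are harmonic inside the mask.
#'
#' @param chi_true 3D susceptibility volume in ppm.
#' @param brain_mask 3D logical array.
#' @param voxel_size_mm Voxel size.
#' @param b0_tesla Field strength.
#' @param b0_direction Unit field direction.
#' @return List of three [field_map()] objects (`db_total`, `db_background`,
#'   `db_local_true`, all in Tesla, full-grid values with the brain mask
#'   attached) plus the `kernel` used.
#' @export
simulate_fields <- function(chi_true, brain_mask, voxel_size_mm = c(1, 1, 1),
                            b0_tesla = 3, b0_direction = c(0, 0, 1)) {
  if (!all(is.finite(chi_true))) stop("chi_true must be finite")
  mask <- as_mask(brain_mask, dim(chi_true))
  if (!any(mask)) stop("brain mask is empty")
  kern <- dipole_kernel(dim(chi_true), voxel_size_mm, b0_direction)
  db_total <- dipole_forward(chi_true, kern, b0_tesla)
  chi_int <- chi_true
  chi_int[!mask] <- 0
  chi_int[mask] <- chi_int[mask] - mean(chi_true[mask])
  db_local <- dipole_forward(chi_int, kern, b0_tesla)
  db_bg <- db_total - db_local
  list(db_total = field_map(db_total, "tesla", "total", mask),
       db_background = field_map(db_bg, "tesla", "background", mask),
       db_local_true = field_map(db_local, "tesla", "local", mask),
       kernel = kern)
}

#' Simulate noisy multi-echo GRE acquisitions from a phantom
#'
#' Generates the noise-free complex signal
#' `S = M0 exp(-TE * R2*) exp(i (gamma * dB_total * TE + phi0))` at each echo
#' and adds independent zero-mean Gaussian noise of SD `spec$noise_sd` to the
#' real and imaginary parts, regenerated at every echo and every repeat.
#' Repeats share the ground truth and differ only in their noise streams,
#' emulating back-to-back scans of the same subject without repositioning.
#'
#' @param ground_truth Output of [build_phantom()] augmented with a
#'   `db_total` field map (see [simulate_fields()]), or a list carrying
#'   `m0_true`, `t2star_true`, `phi0_true` and `db_total`.
#' @param spec The [phantom_spec()].
#' @param n_repeats Number of independent noise realisations (>= 1).
#' @return List of `n_repeats` [multi_echo_gre()] objects.
#' @export
simulate_gre <- function(ground_truth, spec, n_repeats = 1) {
  stopifnot(n_repeats >= 1)
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  shape <- spec$grid_shape
  tes <- spec$echo_times_s
  ne <- length(tes)
  gam <- gyromagnetic_ratio()
  r2s <- 1000 / ground_truth$t2star_true # ms -> s^-1
  db <- field_values_tesla(ground_truth$db_total, spec$b0_tesla)
  phi0 <- ground_truth$phi0_true
  m0 <- ground_truth$m0_true
  nvox <- prod(shape)
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    mag <- array(0, dim = c(shape, ne))
    ph <- array(0, dim = c(shape, ne))
    for (i in seq_len(ne)) {
      m_te <- m0 * exp(-tes[i] * r2s)
      theta <- gam * db * tes[i] + phi0
      re <- m_te * cos(theta)
      im <- m_te * sin(theta)
      if (spec$noise_sd > 0) {
        noise <- withr::with_seed(
          derive_seed(spec$seed, 1000 + 100 * r + i),
          stats::rnorm(2 * nvox, sd = spec$noise_sd))
        re <- re + noise[seq_len(nvox)]
        im <- im + noise[nvox + seq_len(nvox)]
      }
      s <- complex(real = re, imaginary = im)
      mag[, , , i] <- Mod(s)
      ph[, , , i] <- Arg(s)
    }
    out[[r]] <- multi_echo_gre(mag, ph, tes, spec$voxel_size_mm,
                               spec$b0_tesla, spec$b0_direction)
  }
  out
}

#' Morphological erosion of a binary mask
#'
#' Erodes with a full 3x3x3 cubic structuring element applied `radius`
#' times (so "eroded by N voxels" removes an N-voxel rind in the chessboard
#' metric). Radius 0 is the identity.
#'
#' @param mask 3D logical array.
#' @param radius_voxels Non-negative integer erosion radius.
#' @return Eroded logical array; errors if the mask erodes to empty.
#' @export
erode_mask <- function(mask, radius_voxels) {
  stopifnot(radius_voxels >= 0)
  m <- as_mask(mask, dim(mask))
  for (r in seq_len(radius_voxels)) {
    for (ax in 1:3) {
      m <- m & shift_array(m, ax, 1L) & shift_array(m, ax, -1L)
    }
    if (!any(m))
      stop("mask eroded to empty at radius ", r,
           " (requested ", radius_voxels, ")")
  }
  m
}

#' Build a phantom from an external label volume
#'
#' Ingests a voxelised anatomical label volume (for example an externally
#' obtained Zubal head phantom) together with a tissue table, optionally
#' resampling the labels to a target grid by nearest-neighbour lookup, and
#' returns the same ground-truth structure as [build_phantom()].
#'
#' @param labels 3D integer array, or a path to a NIfTI volume of labels.
#' @param name_map Character vector mapping label value `i` to a region name
#'   present in `tissue_table` (labels not named are treated as background).
#' @param tissue_table Tissue property table, see [default_tissue_table()].
#' @param target_shape Optional length-3 grid to resample to.
#' @param spec_args Further arguments passed to [phantom_spec()] (echo times,
#'   noise, seed, ...).
#' @return Same structure as [build_phantom()].
#' @export
phantom_from_labels <- function(labels, name_map,
                                tissue_table = default_tissue_table(),
                                target_shape = NULL, spec_args = list()) {
  if (is.character(labels)) labels <- as.integer(round(RNifti::readNifti(labels)))
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!is.null(target_shape)) {
    src <- dim(labels)
    idx <- lapply(1:3, function(a)
      pmin(pmax(round((seq_len(target_shape[a]) - 0.5) *
                        src[a] / target_shape[a] + 0.5), 1), src[a]))
    labels <- labels[idx[[1]], idx[[2]], idx[[3]]]
  }
  keep <- seq_along(name_map)[!is.na(name_map) & nzchar(name_map)]
  relab <- array(0L, dim = dim(labels))
  for (j in seq_along(keep)) relab[labels == keep[j]] <- j
  names_used <- name_map[keep]
  spec <- do.call(phantom_spec, c(list(
    grid_shape = dim(relab),
    regions = lapply(names_used, function(nm)
      list(region = nm, type = "external")),
    tissue_table = tissue_table), spec_args))
  brain_mask <- relab > 0L
  tt <- tissue_table
  ridx <- match(names_used, tt$region)
  chi <- sample_property(relab, names_used, tt$chi_mean_ppm[ridx],
                         tt$chi_sd_ppm[ridx], derive_seed(spec$seed, 1))
  chi[!brain_mask] <- spec$air_chi_ppm
  m0 <- sample_property(relab, names_used, tt$m0_mean[ridx], tt$m0_sd[ridx],
                        derive_seed(spec$seed, 2), clip_min = 0)
  m0[!brain_mask] <- 0
  t2s <- sample_property(relab, names_used, tt$t2star_mean_ms[ridx],
                         tt$t2star_sd_ms[ridx], derive_seed(spec$seed, 3),
                         clip_min = 1)
  t2s[!brain_mask] <- 1
  list(labels = relab, name_map = names_used, brain_mask = brain_mask,
       chi_true = chi, m0_true = m0, t2star_true = t2s,
       phi0_true = phi0_map(spec), spec = spec)
}
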