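# Shared fixtures, all built in code at test time.

grid_radius <- function(n, center = (n + 1) / 2) {
  X <- array(seq_len(n), dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  list(X = X, Y = Y, Z = Z,
       r = sqrt((X - center)^2 + (Y - center)^2 + (Z - center)^2))
}

# Antialiased sphere of susceptibility `chi` (ppm) at the grid centre.
sphere_chi <- function(n, radius, chi = 1) {
  g <- grid_radius(n)
  pmin(pmax(radius + 0.5 - g$r, 0), 1) * chi
}

# Small piece-wise phantom spec for fast end-to-end tests: a single
# spherical "lesion" inside a spherical "brain", no property variability.
sphere_phantom_spec <- function(n = 48, noise_sd = 0, seed = 101) {
  tt <- tibble::tibble(
    region = c("brain", "lesion"),
    chi_mean_ppm = c(0, 0.2), chi_sd_ppm = c(0, 0),
    m0_mean = c(1, 0.9), m0_sd = c(0, 0),
    t2star_mean_ms = c(60, 30), t2star_sd_ms = c(0, 0))
  regions <- list(
    list(region = "brain", type = "ellipsoid", center = c(0.5, 0.5, 0.5),
         semi_axes = c(0.40, 0.40, 0.40)),
    list(region = "lesion", type = "ellipsoid", center = c(0.5, 0.5, 0.5),
         semi_axes = c(0.08, 0.08, 0.08)))
  phantom_spec(grid_shape = c(n, n, n), regions = regions,
               tissue_table = tt, noise_sd = noise_sd, seed = seed)
}

# Complete simulated acquisition for a spec: phantom, fields, one scan.
simulate_study <- function(spec, n_repeats = 1) {
  ph <- build_phantom(spec)
  flds <- simulate_fields(ph$chi_true, ph$brain_mask, spec$voxel_size_mm,
                          spec$b0_tesla, spec$b0_direction)
  gt <- c(ph, flds["db_total"])
  list(phantom = ph, fields = flds,
       gre = simulate_gre(gt, spec, n_repeats = n_repeats))
}

default_tes <- function() 0.003 + 0.0054 * (0:4)

# Mean of a map over a labelled region intersected with a mask.
region_mean <- function(map, phantom, region, mask = NULL) {
  sel <- phantom$labels %in% which(phantom$name_map == region)
  if (!is.null(mask)) sel <- sel & mask
  mean(map[sel])
}
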