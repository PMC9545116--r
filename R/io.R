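#' Read a multi-echo GRE acquisition from NIfTI volumes
#'
#' Reads 4D magnitude and phase volumes (echo along the 4th axis) and a
#' JSON sidecar with the acquisition metadata. Phase stored in a
#' scaled-integer dialect (e.g. 0..4095) is auto-detected and linearly
#' rescaled onto `(-pi, pi]` with a warning.
#'
#' @param mag_path,phase_path Paths to 4D NIfTI volumes.
#' @param sidecar Path to a JSON file with fields `echo_times_s` (seconds),
#'   `b0_tesla`, `b0_direction`, or a list with those fields.
#' @return A [multi_echo_gre()].
#' @export
read_gre <- function(mag_path, phase_path, sidecar) {
  mag_img <- RNifti::readNifti(mag_path)
  ph_img <- RNifti::readNifti(phase_path)
  vx <- RNifti::pixdim(ph_img)[1:3]
  mag <- array(as.numeric(mag_img), dim = dim(mag_img))
  ph <- array(as.numeric(ph_img), dim = dim(ph_img))
  meta <- if (is.character(sidecar)) jsonlite::read_json(sidecar,
                                                         simplifyVector = TRUE)
          else sidecar
  tes <- as.numeric(meta$echo_times_s)
  if (length(dim(mag)) == 3) dim(mag) <- c(dim(mag), 1)
  if (length(dim(ph)) == 3) dim(ph) <- c(dim(ph), 1)
  if (dim(mag)[4] != length(tes))
    stop("echo-count mismatch between 4D volumes and sidecar")
  rng <- range(ph)
  if (rng[1] >= 0 && rng[2] > pi + 1e-3) {
    vmax <- max(ph)
    warning("phase stored in a scaled-integer dialect [0, ", vmax,
            "]; rescaling to (-pi, pi]")
    ph <- 2 * pi * (ph - vmax / 2) / (vmax + 1)
  }
  ph <- wrap_phase(ph)
  multi_echo_gre(mag, ph, tes,
                 voxel_size_mm = as.numeric(vx),
                 b0_tesla = meta$b0_tesla %||% 3,
                 b0_direction = as.numeric(meta$b0_direction %||% c(0, 0, 1)))
}

#' Write a volume as NIfTI
#'
#' Float32 storage with a diagonal affine built from the voxel size; 3D or
#' 4D arrays are supported. Round-tripping through
#' [read_gre()]/[RNifti::readNifti()] preserves the data to float32
#' precision and the affine exactly.
#'
#' @param volume 3D or 4D numeric array (logical is converted to 0/1).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Length-3 voxel size for the affine.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(1, 1, 1)) {
  v <- volume * 1 # logical -> numeric
  attr(v, "pixdim") <- c(voxel_size_mm, rep(1, length(dim(v)) - 3))
  img <- RNifti::asNifti(v, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated phantom study to disk
#'
#' Writes the ground-truth maps, field maps, mask and one magnitude/phase
#' pair per repeat as NIfTI, plus a JSON sidecar with the acquisition
#' metadata (echo times in seconds, B0, field direction, seed).
#'
#' @param phantom Output of [build_phantom()].
#' @param fields Output of [simulate_fields()].
#' @param gre_list Output of [simulate_gre()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_phantom_study <- function(phantom, fields, gre_list, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vx <- phantom$spec$voxel_size_mm
  write_volume(phantom$chi_true, file.path(out_dir, "chi_true.nii.gz"), vx)
  write_volume(phantom$m0_true, file.path(out_dir, "m0.nii.gz"), vx)
  write_volume(phantom$t2star_true, file.path(out_dir, "t2star.nii.gz"), vx)
  write_volume(phantom$brain_mask, file.path(out_dir, "mask.nii.gz"), vx)
  write_volume(phantom$labels, file.path(out_dir, "labels.nii.gz"), vx)
  write_volume(fields$db_total$values,
               file.path(out_dir, "db_total.nii.gz"), vx)
  write_volume(fields$db_background$values,
               file.path(out_dir, "db_background.nii.gz"), vx)
  write_volume(fields$db_local_true$values,
               file.path(out_dir, "db_local_true.nii.gz"), vx)
  for (r in seq_along(gre_list)) {
    write_volume(gre_list[[r]]$magnitude,
                 file.path(out_dir, sprintf("mag_rep%02d.nii.gz", r)), vx)
    write_volume(gre_list[[r]]$phase,
                 file.path(out_dir, sprintf("phase_rep%02d.nii.gz", r)), vx)
  }
  jsonlite::write_json(
    list(echo_times_s = phantom$spec$echo_times_s,
         b0_tesla = phantom$spec$b0_tesla,
         b0_direction = phantom$spec$b0_direction,
         noise_sd = phantom$spec$noise_sd, seed = phantom$spec$seed,
         region_names = phantom$name_map),
    file.path(out_dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a phantom specification from YAML
#'
#' Accepts the fields of [phantom_spec()]; `regions` and `tissue_table`
#' entries follow the same structure as the defaults.
#'
#' @param path YAML file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("grid_shape", "voxel_size_mm", "b0_tesla", "b0_direction",
               "phi0_model", "noise_sd", "echo_times_s", "air_chi_ppm",
               "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$regions))
    args$regions <- lapply(y$regions, function(r) {
      for (f in c("center", "semi_axes", "half_width", "angle_deg"))
        if (!is.null(r[[f]])) r[[f]] <- unlist(r[[f]])
      r
    })
  if (!is.null(y$tissue_table))
    args$tissue_table <- tibble::as_tibble(
      do.call(rbind, lapply(y$tissue_table, as.data.frame)))
  do.call(phantom_spec, args)
}
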