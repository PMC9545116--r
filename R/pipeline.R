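#' Pipeline configuration
#'
#' Settings for the four multi-echo QSM processing streams. All pipelines
#' share the SHARP settings (3-voxel Laplacian kernel, truncation threshold
#' 0.05, 5-voxel mask erosion), the Laplacian-unwrapping truncation
#' threshold 1e-10 and the Tikhonov inversion; they differ only in where
#' the echoes are combined:
#'
#' * `nlfit` — temporal unwrapping, nonlinear complex fit of the total
#'   field, SHARP, inversion.
#' * `te-wavg` — per-echo Laplacian unwrapping, TE-weighted averaging of
#'   the phase, SHARP, inversion.
#' * `snr-wavg` — per-echo SHARP, R2* mapping, SNR-weighted averaging of
#'   the local phase, inversion.
#' * `susc-wavg` — per-echo SHARP, per-echo inversion, magnitude-weighted
#'   averaging of the susceptibility maps.
#'
#' @param pipeline Pipeline name (see above).
#' @param sharp_threshold SHARP truncation threshold, in (0, 1).
#' @param erode_voxels SHARP mask erosion radius.
#' @param unwrap_threshold Laplacian-unwrapping truncation threshold, in
#'   (0, 1).
#' @param alpha Tikhonov parameter; `NULL` selects it by L-curve.
#' @param alpha_grid Candidate grid for the L-curve.
#' @param correction Underestimation correction: `TRUE` to calibrate on a
#'   synthetic sphere for this grid (cached), a number to use directly, or
#'   `FALSE`/1 for none.
#' @param external_chi Optional 4D array of per-echo susceptibility maps
#'   computed by an external tool; when supplied with
#'   `pipeline = "susc-wavg"`, the per-echo inversions are skipped and the
#'   external maps are combined instead (the hook for plugging in, e.g., a
#'   per-echo single-step reconstruction).
#' @param out_dir Optional directory; when set, the result and all
#'   intermediates are written as NIfTI/JSON.
#' @param verbose Log stage timings to stderr.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(pipeline = c("nlfit", "te-wavg", "snr-wavg",
                                         "susc-wavg"),
                            sharp_threshold = 0.05, erode_voxels = 5,
                            unwrap_threshold = 1e-10, alpha = NULL,
                            alpha_grid = 10^seq(-4, 0, length.out = 30),
                            correction = TRUE, external_chi = NULL,
                            out_dir = NULL, verbose = FALSE) {
  pipeline <- match.arg(pipeline)
  if (sharp_threshold <= 0 || sharp_threshold >= 1 ||
      unwrap_threshold <= 0 || unwrap_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(list(pipeline = pipeline, sharp_threshold = sharp_threshold,
                 erode_voxels = erode_voxels,
                 unwrap_threshold = unwrap_threshold, alpha = alpha,
                 alpha_grid = alpha_grid, correction = correction,
                 external_chi = external_chi, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

pipeline_log <- function(config, stage, t0) {
  if (isTRUE(config$verbose))
    message(sprintf("[%s] %-28s %6.2f s", config$pipeline, stage,
                    as.numeric(proc.time()[3]) - t0))
  invisible(NULL)
}

resolve_alpha <- function(fm, mask, config, gre) {
  if (!is.null(config$alpha)) return(list(alpha = config$alpha, curve = NULL))
  lc <- lcurve_alpha(fm, mask, config$alpha_grid, gre$b0_tesla,
                     gre$voxel_size_mm, gre$b0_direction)
  list(alpha = lc$alpha_star, curve = lc$curve)
}

resolve_correction <- function(config, shape, gre, alpha) {
  corr <- config$correction
  if (isFALSE(corr)) return(1)
  if (is.numeric(corr)) return(corr)
  underestimation_correction(shape, gre$voxel_size_mm, gre$b0_direction,
                             alpha = alpha,
                             tsvd_threshold = config$sharp_threshold,
                             erode_voxels = config$erode_voxels)
}

#' Run a complete multi-echo QSM pipeline
#'
#' Executes one of the four processing streams end-to-end on a multi-echo
#' GRE acquisition and returns the susceptibility map together with every
#' intermediate (combined field maps, per-echo products, weights, eroded
#' mask, regularisation parameter and correction factor). All pipelines
#' report susceptibility on the SHARP-eroded mask only.
#'
#' @param gre A [multi_echo_gre()].
#' @param mask 3D logical brain mask.
#' @param config A [pipeline_config()].
#' @return List: `chi` (a [chi_map()]), `intermediates` (named list,
#'   contents depend on the pipeline; always includes `eroded_mask`,
#'   `alpha`, `correction_factor`, and `db_combined` for the three
#'   field-combining pipelines), `config`.
#' @export
run_pipeline <- function(gre, mask, config = pipeline_config()) {
  stopifnot(inherits(gre, "multi_echo_gre"), inherits(config, "pipeline_config"))
  shape <- dim(gre$magnitude)[1:3]
  mask <- as_mask(mask, shape)
  tes <- gre$echo_times_s
  ne <- length(tes)
  gam <- gyromagnetic_ratio()
  t0 <- as.numeric(proc.time()[3])
  inter <- list()
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline '", config$pipeline, "' failed at stage '", stage,
           "': ", conditionMessage(e), call. = FALSE))
    pipeline_log(config, stage, t0)
    res
  }

  if (config$pipeline == "nlfit") {
    fit <- run_stage("nlfit_complex", nlfit_complex(gre, mask))
    inter$db_total <- fit$db_total
    inter$phi0 <- fit$phi0
    inter$nlfit_residual <- fit$residual
    sh <- run_stage("sharp", sharp(fit$db_total$values, mask,
                                   tsvd_threshold = config$sharp_threshold,
                                   erode_voxels = config$erode_voxels))
    db_loc <- field_map(sh$values, "tesla", "local", sh$eroded_mask)
  } else if (config$pipeline == "te-wavg") {
    unw <- array(0, dim = c(shape, ne))
    run_stage("laplacian_unwrap", for (i in seq_len(ne))
      unw[, , , i] <- laplacian_unwrap(gre$phase[, , , i], mask,
                                       config$unwrap_threshold))
    inter$unwrapped_phase <- unw
    db_tot <- run_stage("te_weighted_average",
                        te_weighted_average(unw, tes, mask))
    inter$db_total <- db_tot
    sh <- run_stage("sharp", sharp(db_tot$values, mask,
                                   tsvd_threshold = config$sharp_threshold,
                                   erode_voxels = config$erode_voxels))
    db_loc <- field_map(sh$values, "tesla", "local", sh$eroded_mask)
  } else if (config$pipeline == "snr-wavg") {
    loc <- array(0, dim = c(shape, ne))
    m_e <- NULL
    run_stage("sharp_per_echo", for (i in seq_len(ne)) {
      s <- sharp(gre$phase[, , , i], mask,
                 tsvd_threshold = config$sharp_threshold,
                 erode_voxels = config$erode_voxels)
      loc[, , , i] <- s$values
      m_e <- s$eroded_mask
    })
    inter$local_phase <- loc
    rel <- run_stage("fit_r2star", fit_r2star(gre$magnitude, tes, mask))
    inter$r2star <- rel$r2star
    inter$m0 <- rel$m0
    db_loc <- run_stage("snr_weighted_average",
                        snr_weighted_average(loc, tes, rel$r2star, m_e))
    inter$weights <- attr(db_loc, "weights")
    db_loc$mask <- m_e
  } else { # susc-wavg
    loc <- array(0, dim = c(shape, ne))
    m_e <- NULL
    run_stage("sharp_per_echo", for (i in seq_len(ne)) {
      s <- sharp(gre$phase[, , , i], mask,
                 tsvd_threshold = config$sharp_threshold,
                 erode_voxels = config$erode_voxels)
      loc[, , , i] <- s$values
      m_e <- s$eroded_mask
    })
    inter$local_phase <- loc
    if (is.null(config$external_chi)) {
      chi_e <- array(0, dim = c(shape, ne))
      alphas <- numeric(ne)
      corrs <- numeric(ne)
      curve <- NULL
      for (i in seq_len(ne)) {
        fm_i <- field_map(loc[, , , i], "radians", "local", m_e,
                          te_s = tes[i])
        sel <- resolve_alpha(fm_i, m_e, config, gre)
        if (i == 1) curve <- sel$curve
        corr_i <- resolve_correction(config, shape, gre, sel$alpha)
        inv <- tikhonov_invert(fm_i, m_e, sel$alpha, gre$b0_tesla, corr_i,
                               gre$voxel_size_mm, gre$b0_direction)
        chi_e[, , , i] <- inv$chi
        alphas[i] <- sel$alpha
        corrs[i] <- corr_i
      }
      pipeline_log(config, "tikhonov_per_echo", t0)
      inter$chi_per_echo <- chi_e
      inter$alpha_per_echo <- alphas
      inter$correction_per_echo <- corrs
      inter$lcurve <- curve
      alpha_used <- stats::median(alphas)
      corr_used <- stats::median(corrs)
    } else {
      chi_e <- config$external_chi
      stopifnot(identical(dim(chi_e), c(shape, ne)))
      inter$chi_per_echo <- chi_e
      alpha_used <- NA_real_
      corr_used <- 1
    }
    comb <- run_stage("susceptibility_weighted_average",
                      susceptibility_weighted_average(chi_e, gre$magnitude,
                                                      tes, m_e))
    inter$weights <- comb$weights
    inter$eroded_mask <- m_e
    inter$alpha <- alpha_used
    inter$correction_factor <- corr_used
    inter$db_combined <- NULL
    chi <- comb$chi
    chi[!m_e] <- 0
    out <- list(chi = chi_map(chi, m_e, gre$b0_tesla, alpha_used, corr_used),
                intermediates = inter, config = config)
    maybe_write_pipeline(out, gre, config)
    return(out)
  }

  # shared tail of the three field-combining pipelines
  inter$db_combined <- db_loc
  sel <- run_stage("alpha_selection", resolve_alpha(db_loc, db_loc$mask,
                                                    config, gre))
  corr <- run_stage("correction",
                    resolve_correction(config, shape, gre, sel$alpha))
  inv <- run_stage("tikhonov_invert",
                   tikhonov_invert(db_loc, db_loc$mask, sel$alpha,
                                   gre$b0_tesla, corr, gre$voxel_size_mm,
                                   gre$b0_direction))
  inter$eroded_mask <- db_loc$mask
  inter$alpha <- sel$alpha
  inter$lcurve <- sel$curve
  inter$correction_factor <- corr
  out <- list(chi = inv, intermediates = inter, config = config)
  maybe_write_pipeline(out, gre, config)
  out
}

maybe_write_pipeline <- function(result, gre, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  vx <- gre$voxel_size_mm
  write_volume(result$chi$chi, file.path(config$out_dir, "chi.nii.gz"), vx)
  write_volume(result$intermediates$eroded_mask * 1,
               file.path(config$out_dir, "mask_eroded.nii.gz"), vx)
  if (!is.null(result$intermediates$db_combined))
    write_volume(result$intermediates$db_combined$values,
                 file.path(config$out_dir, "db_combined.nii.gz"), vx)
  jsonlite::write_json(
    list(pipeline = config$pipeline, alpha = result$intermediates$alpha,
         correction_factor = result$intermediates$correction_factor,
         echo_times_s = gre$echo_times_s, b0_tesla = gre$b0_tesla,
         b0_direction = gre$b0_direction),
    file.path(config$out_dir, "pipeline.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
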