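#' Two-scan SNR-difference noise estimation
#'
#' Estimates per-ROI magnitude and phase noise from two back-to-back scans
#' acquired without repositioning: per ROI and echo,
#' `M_ROI = mean((M1 + M2)/2)`, `sigma_ROI(M) = sqrt(R/2) SD(M1 - M2)` and
#' `sigma_ROI(phi) = sqrt(R/2) SD(phi1 - phi2)`, where `R` is the 2D SENSE
#' acceleration factor (the product of the per-axis factors; `R = 1` gives
#' the textbook two-scan difference method). Per-echo summary values are
#' the averages across ROIs.
#'
#' @param scan1,scan2 Two co-registered [multi_echo_gre()] objects with the
#'   same echoes.
#' @param rois Named list of 3D logical ROI masks.
#' @param sense_factor_r SENSE factor `R` (default 3, a 2 x 1.5 protocol).
#' @return List: `roi_stats` (tibble: roi, echo, te_s, m_roi, sigma_m,
#'   sigma_phi), `summary` (tibble per echo, ROI-averaged), `sense_factor_r`.
#' @export
snr_difference <- function(scan1, scan2, rois, sense_factor_r = 3) {
  stopifnot(inherits(scan1, "multi_echo_gre"), inherits(scan2, "multi_echo_gre"))
  if (!isTRUE(all.equal(scan1$echo_times_s, scan2$echo_times_s)))
    stop("mismatched echo times between scans")
  if (!identical(dim(scan1$magnitude), dim(scan2$magnitude)))
    stop("mismatched scan geometries")
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  tes <- scan1$echo_times_s
  ne <- length(tes)
  shape <- dim(scan1$magnitude)[1:3]
  rows <- list()
  for (nm in names(rois)) {
    sel <- as_mask(rois[[nm]], shape)
    if (!any(sel)) stop("ROI '", nm, "' is empty")
    for (i in seq_len(ne)) {
      m1 <- scan1$magnitude[, , , i][sel]
      m2 <- scan2$magnitude[, , , i][sel]
      p1 <- scan1$phase[, , , i][sel]
      p2 <- scan2$phase[, , , i][sel]
      dphi <- wrap_phase(p1 - p2) # difference of wrapped phases, re-centred
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = nm, echo = i, te_s = tes[i],
        m_roi = mean((m1 + m2) / 2),
        sigma_m = sqrt(sense_factor_r / 2) * stats::sd(m1 - m2),
        sigma_phi = sqrt(sense_factor_r / 2) * stats::sd(dphi))
    }
  }
  roi_stats <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(roi_stats, roi_stats$echo),
    function(d) tibble::tibble(echo = d$echo[1], te_s = d$te_s[1],
                               m_roi = mean(d$m_roi),
                               sigma_m = mean(d$sigma_m),
                               sigma_phi = mean(d$sigma_phi))))
  list(roi_stats = roi_stats, summary = summary,
       sense_factor_r = sense_factor_r)
}

#' Per-voxel phase-noise map from the magnitude image
#'
#' At high SNR the phase noise is the reciprocal image SNR:
#' `sigma_phi(r) = c * sigma_M / M(r)`. The calibration constant `c(TE)`
#' equals 1 by definition for simulated data (complex channel noise maps
#' directly onto magnitude noise) and is estimated from the two-scan ROI
#' statistics for measured data.
#'
#' @param magnitude_3d 3D magnitude at one echo.
#' @param sigma_m_roi Scalar magnitude noise at that echo.
#' @param c_te Calibration constant (default 1).
#' @return List: `sigma_phi` (3D radians; `Inf` flags zero-magnitude
#'   voxels), `flagged` (3D logical).
#' @export
phase_noise_map <- function(magnitude_3d, sigma_m_roi, c_te = 1) {
  zero <- magnitude_3d <= 0
  s <- c_te * sigma_m_roi / magnitude_3d
  s[zero] <- Inf
  list(sigma_phi = s, flagged = zero)
}

#' Calibration constant c(TE) from two-scan ROI statistics
#'
#' `c(TE) = sigma_ROI(phi) * M_ROI / sigma_ROI(M)`: the ratio of the
#' measured phase noise to the reciprocal ROI SNR. Approximately 1 wherever
#' the complex-noise model holds.
#'
#' @param roi_summary Per-echo summary tibble from [snr_difference()].
#' @return Numeric vector `c(TE)`, one value per echo.
#' @export
c_of_te <- function(roi_summary) {
  roi_summary$sigma_phi * roi_summary$m_roi / roi_summary$sigma_m
}

#' Analytic field noise of the (non)linear multi-echo fit
#'
#' Weighted-least-squares slope variance of the phase-vs-TE line with
#' per-echo weights `1/sigma_phi^2`: with moments `S0 = sum 1/s^2`,
#' `S1 = sum TE/s^2`, `S2 = sum TE^2/s^2`,
#' `sigma(dB_total) = (1/gamma) sqrt(S0 / (S0 S2 - S1^2))`. This is also
#' the a-priori noise of the nonlinear complex fit, which shares the same
#' information content at high SNR.
#'
#' @param sigma_phi_per_echo Per-echo phase-noise maps: 4D array (or a
#'   vector of per-echo scalars), radians.
#' @param echo_times_s Echo times, seconds (>= 2).
#' @return Field-noise map (3D array, Tesla) or scalar for scalar input.
#' @export
sigma_field_fit <- function(sigma_phi_per_echo, echo_times_s) {
  tes <- echo_times_s
  if (length(tes) < 2) stop("at least 2 echoes required")
  gam <- gyromagnetic_ratio()
  per_echo <- echo_maps(sigma_phi_per_echo, length(tes))
  s0 <- s1 <- s2 <- 0
  for (i in seq_along(tes)) {
    w <- 1 / per_echo[[i]]^2
    s0 <- s0 + w
    s1 <- s1 + tes[i] * w
    s2 <- s2 + tes[i]^2 * w
  }
  sqrt(s0 / (s0 * s2 - s1^2)) / gam
}

#' Analytic field noise of TE-weighted averaging
#'
#' With temporally uncorrelated per-echo phase noise,
#' `sigma(dB_total) = sqrt(sum sigma_phi(TE_i)^2) / (gamma sum TE_j)`.
#' A single echo reduces to `sigma_phi / (gamma TE)`.
#'
#' @inheritParams sigma_field_fit
#' @return Field-noise map (or scalar), Tesla.
#' @export
sigma_field_tewavg <- function(sigma_phi_per_echo, echo_times_s) {
  tes <- echo_times_s
  if (length(tes) < 1) stop("at least 1 echo required")
  gam <- gyromagnetic_ratio()
  per_echo <- echo_maps(sigma_phi_per_echo, length(tes))
  acc <- 0
  for (i in seq_along(tes)) acc <- acc + per_echo[[i]]^2
  sqrt(acc) / (gam * sum(tes))
}

#' Analytic field noise of SNR-weighted averaging
#'
#' First-order propagation through the R2*-dependent weights:
#' `sigma(dB_local) = (1/gamma) sqrt( sum_i [exp(-TE_i R2*) /
#' sum_j TE_j exp(-TE_j R2*)]^2 sigma_phi(TE_i)^2 )`. Reduces exactly to
#' [sigma_field_tewavg()] at `R2* = 0`.
#'
#' @inheritParams sigma_field_fit
#' @param r2star 3D non-negative R2* map (or scalar), s^-1.
#' @return Field-noise map (or scalar), Tesla.
#' @export
sigma_field_snrwavg <- function(sigma_phi_per_echo, echo_times_s, r2star) {
  tes <- echo_times_s
  if (length(tes) < 1) stop("at least 1 echo required")
  if (any(r2star < 0)) stop("r2star must be non-negative")
  gam <- gyromagnetic_ratio()
  per_echo <- echo_maps(sigma_phi_per_echo, length(tes))
  denom <- 0
  for (j in seq_along(tes)) denom <- denom + tes[j] * exp(-tes[j] * r2star)
  acc <- 0
  for (i in seq_along(tes))
    acc <- acc + (exp(-tes[i] * r2star) / denom)^2 * per_echo[[i]]^2
  sqrt(acc) / gam
}

# Normalise per-echo sigma input: 4D array, list of 3D maps, or numeric
# vector of scalars -> list of per-echo values.
echo_maps <- function(x, ne) {
  if (is.list(x)) {
    stopifnot(length(x) == ne)
    x
  } else if (is.array(x) && length(dim(x)) == 4) {
    stopifnot(dim(x)[4] == ne)
    lapply(seq_len(ne), function(i) x[, , , i])
  } else if (is.numeric(x)) {
    stopifnot(length(x) == ne)
    as.list(x)
  } else stop("unsupported per-echo sigma input")
}

#' Susceptibility-noise map from a field-noise map
#'
#' First-order propagation of voxel-wise field noise through the linear
#' Tikhonov inversion. The inversion is a circular convolution with the
#' impulse response `h = IFFT[D/(D^2 + alpha)]`, so the variance map is
#' convolved with `h^2`:
#' `sigma_chi^2(r) = sum_r' h^2(r - r') sigma_ppm^2(r')`, evaluated by FFT.
#' For spatially uniform input this reduces to the closed form
#' `sigma_ppm * sqrt(sum_k (D/(D^2+alpha))^2 / N)`. Tiny negative values
#' from the FFT round trip are clipped at zero before the square root. The
#' worst-case convention `sigma(dB_local) = sigma(dB_total)` is used by the
#' pipeline wrappers whenever the background-removal noise attenuation is
#' unknown.
#'
#' @param sigma_db_3d 3D field-noise map, Tesla.
#' @param kernel A [dipole_kernel()] with `alpha` set.
#' @param b0_tesla Field strength.
#' @param correction_factor Underestimation-correction scale applied to the
#'   output (the corrected chi map scales the noise identically).
#' @return 3D susceptibility-noise map, ppm.
#' @export
sigma_chi_fourier <- function(sigma_db_3d, kernel, b0_tesla = 3,
                              correction_factor = 1) {
  if (!inherits(kernel, "dipole_kernel")) stop("kernel must be a dipole_kernel")
  if (!is.finite(kernel$alpha)) stop("kernel$alpha must be set")
  var_ppm <- field_to_ppm(sigma_db_3d, b0_tesla)^2
  dinv <- kernel$d_k / (kernel$d_k^2 + kernel$alpha)
  h <- Re(ifft3(dinv))
  v <- Re(ifft3(fft3(h^2) * fft3(var_ppm)))
  v[v < 0] <- 0
  correction_factor * sqrt(v)
}

#' Susceptibility-noise map of magnitude-weighted susceptibility averaging
#'
#' First-order propagation of `chi = sum_i w_i chi_i` with
#' `w_i = M_i^2 TE_i^2 / sum_j M_j^2 TE_j^2` through both the per-echo
#' susceptibility uncertainties and the magnitude dependence of the
#' weights: `sigma_chi^2 = sum_i (dchi/dM_i)^2 sigma_M_i^2 +
#' sum_i w_i^2 sigma_chi_i^2`, with the analytic sensitivity
#' `dchi/dM_i = (2 M_i TE_i^2 / sum_j M_j^2 TE_j^2) (chi_i - chi)`.
#' A single echo degenerates to that echo's sigma (constant unit weight).
#'
#' @param chi_per_echo 4D per-echo susceptibility maps, ppm.
#' @param sigma_chi_per_echo 4D per-echo susceptibility-noise maps, ppm
#'   (each from [sigma_chi_fourier()] at that echo).
#' @param magnitude_per_echo 4D magnitude array.
#' @param sigma_m_per_echo Per-echo magnitude noise (vector of scalars or
#'   4D array).
#' @param echo_times_s Echo times, seconds.
#' @return List: `sigma_chi` (3D, ppm), `flagged` (3D logical: zero total
#'   weight, output set to 0).
#' @export
sigma_chi_suscwavg <- function(chi_per_echo, sigma_chi_per_echo,
                               magnitude_per_echo, sigma_m_per_echo,
                               echo_times_s) {
  tes <- echo_times_s
  ne <- length(tes)
  stopifnot(dim(chi_per_echo)[4] == ne,
            identical(dim(chi_per_echo), dim(magnitude_per_echo)))
  shape <- dim(chi_per_echo)[1:3]
  sig_m <- echo_maps(sigma_m_per_echo, ne)
  sig_c <- echo_maps(sigma_chi_per_echo, ne)
  wsum <- array(0, dim = shape)
  for (j in seq_len(ne))
    wsum <- wsum + magnitude_per_echo[, , , j]^2 * tes[j]^2
  flagged <- wsum == 0
  wsum[flagged] <- 1
  comb <- susceptibility_weighted_average(chi_per_echo, magnitude_per_echo,
                                          tes)
  var <- array(0, dim = shape)
  for (i in seq_len(ne)) {
    wi <- magnitude_per_echo[, , , i]^2 * tes[i]^2 / wsum
    dchidm <- 2 * magnitude_per_echo[, , , i] * tes[i]^2 / wsum *
      (chi_per_echo[, , , i] - comb$chi)
    var <- var + dchidm^2 * sig_m[[i]]^2 + wi^2 * sig_c[[i]]^2
  }
  var[flagged] <- 0
  list(sigma_chi = sqrt(var), flagged = flagged)
}

#' Monte-Carlo noise maps for a full pipeline
#'
#' Reruns the named pipeline on `n_repeats` independent noise realisations
#' of the same ground truth and returns voxel-wise SD maps of the combined
#' field and susceptibility. This is the empirical oracle against which all
#' analytic noise formulas in this module are validated.
#'
#' @param pipeline One of `"nlfit"`, `"te-wavg"`, `"snr-wavg"`,
#'   `"susc-wavg"`.
#' @param phantom Output of [build_phantom()].
#' @param n_repeats Number of noise realisations (>= 50 for stable SDs;
#'   smaller values are allowed for smoke testing).
#' @param seed Master seed for the noise streams.
#' @param config A [pipeline_config()]; fix `alpha` and
#'   `correction_factor` here so repeats share the inversion context.
#' @return List: `sd_db` (3D Tesla, SD of the combined field), `sd_chi`
#'   (3D ppm), `mean_chi` (3D ppm), `mask` (the pipeline's eroded mask),
#'   `n_repeats`.
#' @export
monte_carlo_sigma <- function(pipeline, phantom, n_repeats, seed = 1,
                              config = NULL) {
  pipeline <- match.arg(pipeline, c("nlfit", "te-wavg", "snr-wavg", "susc-wavg"))
  spec <- phantom$spec
  flds <- simulate_fields(phantom$chi_true, phantom$brain_mask,
                          spec$voxel_size_mm, spec$b0_tesla, spec$b0_direction)
  gt <- c(phantom, flds["db_total"])
  if (is.null(config)) config <- pipeline_config(pipeline)
  config$pipeline <- pipeline
  sum_db <- sum2_db <- sum_chi <- sum2_chi <- 0
  mask <- NULL
  for (r in seq_len(n_repeats)) {
    spec_r <- spec
    spec_r$seed <- derive_seed(seed, r)
    gre <- simulate_gre(gt, spec_r, n_repeats = 1)[[1]]
    res <- run_pipeline(gre, phantom$brain_mask, config)
    chi <- res$chi$chi
    if (!is.null(res$intermediates$db_combined)) {
      db <- field_values_tesla(res$intermediates$db_combined, spec$b0_tesla)
      sum_db <- sum_db + db
      sum2_db <- sum2_db + db^2
    }
    sum_chi <- sum_chi + chi
    sum2_chi <- sum2_chi + chi^2
    mask <- res$chi$mask
  }
  n <- n_repeats
  sd_of <- function(s, s2) sqrt(pmax((s2 - s^2 / n) / (n - 1), 0))
  sd_db <- if (is.array(sum2_db)) sd_of(sum_db, sum2_db) else NULL
  list(sd_db = sd_db, sd_chi = sd_of(sum_chi, sum2_chi),
       mean_chi = sum_chi / n, mask = mask, n_repeats = n)
}

#' Analytic susceptibility-noise map for a complete pipeline
#'
#' Chains the analytic noise propagation for one processing stream: the
#' per-echo phase-noise maps `sigma_phi = c * sigma_M / M` (with `c = 1`
#' and `sigma_M` equal to the complex channel noise for simulated data),
#' the combined-field noise of the pipeline's combination rule, the
#' worst-case convention `sigma(dB_local) = sigma(dB_total)` where the
#' background-removal attenuation is unknown, and the Fourier-domain
#' propagation through the Tikhonov inversion. For the
#' susceptibility-averaging pipeline the per-echo field noise
#' `sigma_phi(TE_i) / (gamma TE_i)` is propagated through a per-echo
#' inversion and the magnitude-dependent combination weights.
#'
#' @param pipeline One of `"nlfit"`, `"te-wavg"`, `"snr-wavg"`,
#'   `"susc-wavg"`.
#' @param gre A [multi_echo_gre()] supplying the magnitude maps.
#' @param sigma_m Per-echo magnitude noise: a scalar (applied to every
#'   echo), a length-`n_echo` vector, or the per-echo summary from
#'   [snr_difference()].
#' @param mask 3D logical array over which noise is evaluated (typically
#'   the SHARP-eroded mask); the variance is zero outside.
#' @param alpha Tikhonov parameter of the pipeline's inversion (scalar, or
#'   per-echo vector for `"susc-wavg"`).
#' @param correction_factor Underestimation-correction scale of the
#'   pipeline's inversion (scalar, or per-echo vector for `"susc-wavg"`).
#' @param r2star R2* map, required for `"snr-wavg"`.
#' @param chi_per_echo Per-echo susceptibility maps, required for
#'   `"susc-wavg"` (the weight-sensitivity term depends on them).
#' @param c_te Per-echo calibration constants (default 1).
#' @return List: `sigma_chi` (3D ppm, zero outside the mask), `sigma_db`
#'   (3D Tesla; the combined-field noise, `NULL` for `"susc-wavg"`),
#'   `sigma_phi` (4D per-echo phase noise).
#' @export
pipeline_sigma_chi <- function(pipeline, gre, sigma_m, mask, alpha,
                               correction_factor = 1, r2star = NULL,
                               chi_per_echo = NULL, c_te = 1) {
  pipeline <- match.arg(pipeline, c("nlfit", "te-wavg", "snr-wavg", "susc-wavg"))
  stopifnot(inherits(gre, "multi_echo_gre"))
  tes <- gre$echo_times_s
  ne <- length(tes)
  shape <- dim(gre$magnitude)[1:3]
  mask <- as_mask(mask, shape)
  gam <- gyromagnetic_ratio()
  if (is.data.frame(sigma_m)) sigma_m <- sigma_m$sigma_m
  if (length(sigma_m) == 1) sigma_m <- rep(sigma_m, ne)
  if (length(c_te) == 1) c_te <- rep(c_te, ne)
  sig_phi <- array(0, dim = c(shape, ne))
  for (i in seq_len(ne)) {
    s <- phase_noise_map(gre$magnitude[, , , i], sigma_m[i], c_te[i])$sigma_phi
    s[!mask | !is.finite(s)] <- 0
    sig_phi[, , , i] <- s
  }
  kern <- function(a) dipole_kernel(shape, gre$voxel_size_mm,
                                    gre$b0_direction, alpha = a)
  zero_outside <- function(x) { x[!mask] <- 0; x }
  if (pipeline == "susc-wavg") {
    if (is.null(chi_per_echo))
      stop("chi_per_echo required for the susc-wavg noise map")
    if (length(alpha) == 1) alpha <- rep(alpha, ne)
    if (length(correction_factor) == 1)
      correction_factor <- rep(correction_factor, ne)
    sig_chi_e <- array(0, dim = c(shape, ne))
    for (i in seq_len(ne)) {
      sdb_i <- zero_outside(sig_phi[, , , i] / (gam * tes[i]))
      sig_chi_e[, , , i] <- sigma_chi_fourier(sdb_i, kern(alpha[i]),
                                              gre$b0_tesla,
                                              correction_factor[i])
    }
    prop <- sigma_chi_suscwavg(chi_per_echo, sig_chi_e, gre$magnitude,
                               as.list(sigma_m), tes)
    return(list(sigma_chi = zero_outside(prop$sigma_chi), sigma_db = NULL,
                sigma_phi = sig_phi))
  }
  sig_db <- switch(pipeline,
    "nlfit" = {
      s <- sig_phi
      s[s == 0] <- Inf # excluded voxels cannot carry information
      out <- sigma_field_fit(s, tes)
      out[!is.finite(out)] <- 0
      out
    },
    "te-wavg" = sigma_field_tewavg(sig_phi, tes),
    "snr-wavg" = {
      if (is.null(r2star)) stop("r2star required for the snr-wavg noise map")
      sigma_field_snrwavg(sig_phi, tes, r2star)
    })
  sig_db <- zero_outside(sig_db)
  sig_chi <- sigma_chi_fourier(sig_db, kern(alpha[1]), gre$b0_tesla,
                               correction_factor[1])
  list(sigma_chi = zero_outside(sig_chi), sigma_db = sig_db,
       sigma_phi = sig_phi)
}
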