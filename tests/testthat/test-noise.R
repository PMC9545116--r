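gam <- gyromagnetic_ratio()
tes <- default_tes()

test_that("snr difference method: trivial and simulated cases", {
  spec <- sphere_phantom_spec(n = 22, noise_sd = 0.07, seed = 31)
  st <- simulate_study(spec, n_repeats = 2)
  # identical scans -> all sigma zero
  same <- snr_difference(st$gre[[1]], st$gre[[1]],
                         list(core = st$phantom$labels > 0),
                         sense_factor_r = 3)
  expect_true(all(same$roi_stats$sigma_m == 0))
  expect_true(all(same$roi_stats$sigma_phi == 0))
  # two repeats at R = 1: sigma_m recovers the channel noise at high SNR
  core <- st$phantom$brain_mask & st$phantom$m0_true > 0.5
  est <- snr_difference(st$gre[[1]], st$gre[[2]], list(core = core),
                        sense_factor_r = 1)
  expect_equal(est$summary$sigma_m[1], 0.07, tolerance = 0.05)
  # c(TE) ~ 1 for simulated data
  expect_equal(c_of_te(est$summary), rep(1, 5), tolerance = 0.12)
  expect_error(snr_difference(st$gre[[1]], st$gre[[2]], list(bad = core & FALSE)),
               "empty")
})

test_that("phase noise map is reciprocal image SNR", {
  m <- array(1, dim = c(2, 2, 2))
  pm <- phase_noise_map(m, 0.07)
  expect_equal(pm$sigma_phi, array(0.07, dim = c(2, 2, 2)))
  pm2 <- phase_noise_map(2 * m, 0.07)
  expect_equal(pm2$sigma_phi, pm$sigma_phi / 2)
  m[1, 1, 1] <- 0
  pm3 <- phase_noise_map(m, 0.07)
  expect_true(is.infinite(pm3$sigma_phi[1, 1, 1]))
  expect_true(pm3$flagged[1, 1, 1])
})

test_that("analytic field-noise formulas: closed-form values", {
  # equal sigma over the default echo train
  expect_equal(sigma_field_fit(rep(0.07, 5), tes), 1.532e-8,
               tolerance = 1e-3)
  expect_equal(sigma_field_tewavg(rep(0.07, 5), tes),
               sqrt(5) * 0.07 / (gam * sum(tes)), tolerance = 1e-12)
  expect_equal(sigma_field_tewavg(rep(0.07, 5), tes), 8.48e-9,
               tolerance = 1e-3)
  # homogeneity of degree one in sigma
  s <- c(0.05, 0.06, 0.08, 0.1, 0.15)
  expect_equal(sigma_field_fit(3 * s, tes), 3 * sigma_field_fit(s, tes),
               tolerance = 1e-12)
  expect_equal(sigma_field_tewavg(3 * s, tes),
               3 * sigma_field_tewavg(s, tes), tolerance = 1e-12)
  expect_equal(sigma_field_snrwavg(3 * s, tes, 40),
               3 * sigma_field_snrwavg(s, tes, 40), tolerance = 1e-12)
  # n = 2 fit reduces to the two-point slope SD
  s2 <- c(0.07, 0.11)
  t2 <- tes[c(1, 4)]
  expect_equal(sigma_field_fit(s2, t2),
               sqrt(sum(s2^2)) / (gam * abs(diff(t2))), tolerance = 1e-12)
  # n = 1 TE average reduces to sigma/(gamma TE)
  expect_equal(sigma_field_tewavg(0.07, tes[1]), 0.07 / (gam * tes[1]))
  # R2* = 0 reduction
  expect_equal(sigma_field_snrwavg(s, tes, 0), sigma_field_tewavg(s, tes),
               tolerance = 1e-12)
  # TE-wAvg noise never exceeds the worst single-echo noise
  worst <- max(s / (gam * tes))
  expect_lt(sigma_field_tewavg(s, tes), worst)
})

test_that("sigma_chi_fourier matches the k-space sum for uniform input", {
  n <- 24
  kern <- dipole_kernel(c(n, n, n), alpha = 0.05)
  s <- 1.2e-8
  out <- sigma_chi_fourier(array(s, dim = c(n, n, n)), kern, b0_tesla = 3)
  dinv <- kern$d_k / (kern$d_k^2 + kern$alpha)
  expected <- (s / 3e-6) * sqrt(sum(dinv^2) / n^3)
  expect_equal(mean(out), expected, tolerance = 1e-6)
  expect_lt(stats::sd(out) / mean(out), 1e-6) # uniform in, uniform out
  # zero in, zero out; correction scales linearly
  expect_equal(max(sigma_chi_fourier(array(0, dim = c(n, n, n)), kern)), 0)
  out2 <- sigma_chi_fourier(array(s, dim = c(n, n, n)), kern,
                            correction_factor = 1.4)
  expect_equal(out2, 1.4 * out, tolerance = 1e-12)
  kern$alpha <- NA_real_
  expect_error(sigma_chi_fourier(array(s, dim = c(n, n, n)), kern), "alpha")
})

test_that("susc-wavg propagation: degenerate reductions", {
  n <- 3
  shape4 <- c(n, n, n, 1)
  chi <- array(0.1, dim = shape4)
  mag <- array(0.8, dim = shape4)
  sc <- array(0.02, dim = shape4)
  # single echo: weights are 1, no magnitude sensitivity
  out <- sigma_chi_suscwavg(chi, sc, mag, 0.07, tes[1])
  expect_equal(out$sigma_chi, array(0.02, dim = c(n, n, n)),
               tolerance = 1e-12)
  # all-zero uncertainties -> zero
  out0 <- sigma_chi_suscwavg(chi, 0 * sc, mag, 0, tes[1])
  expect_equal(max(out0$sigma_chi), 0)
  # zero-magnitude voxels flagged
  mag5 <- array(0.8, dim = c(n, n, n, 5))
  chi5 <- array(0.1, dim = c(n, n, n, 5))
  sc5 <- array(0.02, dim = c(n, n, n, 5))
  mag5[1, 1, 1, ] <- 0
  out5 <- sigma_chi_suscwavg(chi5, sc5, mag5, rep(0.07, 5), tes)
  expect_true(out5$flagged[1, 1, 1])
  expect_equal(out5$sigma_chi[1, 1, 1], 0)
})

test_that("monte carlo oracle: zero-noise, determinism and scaling", {
  spec <- sphere_phantom_spec(n = 24, noise_sd = 0, seed = 41)
  ph <- build_phantom(spec)
  cfg <- pipeline_config("te-wavg", alpha = 0.05, correction = 1,
                         erode_voxels = 2)
  mc0 <- monte_carlo_sigma("te-wavg", ph, n_repeats = 3, seed = 1,
                           config = cfg)
  expect_lt(max(mc0$sd_chi), 1e-6) # identical repeats, cancellation noise only
  # empirical SD scales linearly with noise_sd at high SNR
  spec1 <- sphere_phantom_spec(n = 24, noise_sd = 0.035, seed = 41)
  spec2 <- sphere_phantom_spec(n = 24, noise_sd = 0.07, seed = 41)
  mc1 <- monte_carlo_sigma("te-wavg", build_phantom(spec1), 12, seed = 2,
                           config = cfg)
  mc2 <- monte_carlo_sigma("te-wavg", build_phantom(spec2), 12, seed = 2,
                           config = cfg)
  m <- mc1$mask
  ratio <- mean(mc1$sd_chi[m]) / mean(mc2$sd_chi[m])
  expect_equal(ratio, 0.5, tolerance = 0.1)
  # seed-fixed reruns are bit-identical
  mc2b <- monte_carlo_sigma("te-wavg", build_phantom(spec2), 12, seed = 2,
                            config = cfg)
  expect_identical(mc2$sd_chi, mc2b$sd_chi)
  expect_error(monte_carlo_sigma("unknown", ph, 3), "arg")
})
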