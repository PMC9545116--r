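gam <- gyromagnetic_ratio()

test_that("temporal unwrapping recovers wrap-free and wrapped series", {
  tes <- default_tes()
  # wrap-free series is unchanged
  ph <- array(0, dim = c(3, 3, 3, 5))
  for (i in 1:5) ph[, , , i] <- 0.3 * i / 5
  expect_equal(temporal_unwrap(ph, tes), ph)
  # a series that wraps at echo 3 is restored exactly
  b <- 0.35e-6 * 3 # strong field, wraps within the echo train
  tru <- array(0, dim = c(2, 2, 2, 5))
  wrp <- tru
  for (i in 1:5) {
    tru[, , , i] <- gam * b * tes[i]
    wrp[, , , i] <- qsmme:::wrap_phase(tru[, , , i])
  }
  expect_false(identical(wrp, tru)) # wraps actually occur
  expect_equal(temporal_unwrap(wrp, tes), tru, tolerance = 1e-12)
  # adding 2*pi to every echo leaves the wrapped input unchanged
  wrp2 <- array(0, dim = dim(wrp))
  for (i in 1:5) wrp2[, , , i] <- qsmme:::wrap_phase(tru[, , , i] + 2 * pi)
  expect_equal(wrp2, wrp, tolerance = 1e-12)
  # single echo: identity with a warning
  expect_warning(out <- temporal_unwrap(wrp[, , , 1, drop = FALSE], tes[1]),
                 "single echo")
  expect_identical(out, wrp[, , , 1, drop = FALSE])
})

test_that("laplacian unwrapping is near-identity on smooth unwrapped phase", {
  n <- 32
  g <- grid_radius(n)
  mask <- g$r <= 13
  smooth <- 0.2 * exp(-g$r^2 / (2 * 6^2)) # small amplitude, no wraps
  out <- laplacian_unwrap(smooth, mask)
  ref <- smooth - mean(smooth[mask])
  inner <- g$r <= 10
  expect_lt(sqrt(mean((out[inner] - ref[inner])^2)), 1e-5)
  # idempotence on its own output
  out2 <- laplacian_unwrap(out, mask)
  expect_lt(sqrt(mean((out2[inner] - (out - mean(out[mask]))[inner])^2)),
            1e-5)
})

test_that("laplacian unwrapping input validation", {
  x <- array(0, dim = c(8, 8, 8))
  expect_error(laplacian_unwrap(x, tsvd_threshold = 1), "truncates")
  x[1] <- NA
  expect_error(laplacian_unwrap(x), "finite")
})

test_that("nlfit recovers field and offset from noiseless data", {
  tes <- default_tes()
  n <- 4
  db <- array(0.02 * 3e-6, dim = c(n, n, n))
  mag <- array(0, dim = c(n, n, n, 5))
  ph <- mag
  for (i in 1:5) {
    mag[, , , i] <- exp(-tes[i] * 20)
    ph[, , , i] <- qsmme:::wrap_phase(gam * db * tes[i] + 0.5)
  }
  fit <- nlfit_complex(multi_echo_gre(mag, ph, tes))
  expect_lt(max(abs(fit$db_total$values - db) / db), 1e-6)
  expect_lt(max(abs(fit$phi0 - 0.5)), 1e-6)

  # two-echo input reduces to the exact two-point line
  g2 <- multi_echo_gre(mag[, , , 1:2, drop = FALSE],
                       ph[, , , 1:2, drop = FALSE], tes[1:2])
  fit2 <- nlfit_complex(g2)
  slope <- (ph[1, 1, 1, 2] - ph[1, 1, 1, 1]) / (gam * (tes[2] - tes[1]))
  expect_equal(fit2$db_total$values[1, 1, 1], slope, tolerance = 1e-10)
})

test_that("nlfit is invariant to a global phase rotation", {
  tes <- default_tes()
  set.seed(8)
  n <- 5
  mag <- array(runif(n^3 * 5, 0.5, 1), dim = c(n, n, n, 5))
  ph <- array(runif(n^3 * 5, -0.5, 0.5), dim = c(n, n, n, 5))
  theta <- 0.9
  f0 <- nlfit_complex(multi_echo_gre(mag, ph, tes))
  f1 <- nlfit_complex(multi_echo_gre(mag, qsmme:::wrap_phase(ph + theta),
                                     tes))
  expect_equal(f1$db_total$values, f0$db_total$values, tolerance = 1e-6)
  expect_equal(qsmme:::wrap_phase(f1$phi0 - f0$phi0 - theta),
               array(0, dim = c(n, n, n)), tolerance = 1e-6)
})

test_that("nlfit flags zero-magnitude voxels", {
  tes <- default_tes()
  mag <- array(1, dim = c(2, 2, 2, 5))
  mag[1, 1, 1, ] <- 0
  ph <- array(0.1, dim = c(2, 2, 2, 5))
  fit <- nlfit_complex(multi_echo_gre(mag, ph, tes))
  expect_equal(fit$db_total$values[1, 1, 1], 0)
  expect_equal(fit$phi0[1, 1, 1], 0)
  expect_true(is.nan(fit$residual[1, 1, 1]))
  expect_false(anyNA(fit$residual[-1]))
})

test_that("sharp removes exterior-source harmonic fields", {
  n <- 48
  g <- grid_radius(n)
  mask <- g$r <= 18
  # source well outside the mask
  r_ext <- sqrt((g$X - 3)^2 + (g$Y - (n + 1) / 2)^2 + (g$Z - (n + 1) / 2)^2)
  chi_ext <- pmin(pmax(4.5 - r_ext, 0), 1) * 2
  f_ext <- simulate_fields(chi_ext, array(TRUE, dim = c(n, n, n)))
  sh <- sharp(f_ext$db_total$values, mask)
  me <- sh$eroded_mask
  input_rms <- sqrt(mean((f_ext$db_total$values[me] -
                            mean(f_ext$db_total$values[me]))^2))
  expect_lt(sqrt(mean(sh$values[me]^2)) / input_rms, 0.02)
  expect_equal(mean(sh$values[me]), 0, tolerance = 1e-20)
  expect_true(all(sh$values[!me] == 0))
})

test_that("sharp recovers an interior dipole field under background", {
  n <- 48
  g <- grid_radius(n)
  mask <- g$r <= 18
  chi_int <- sphere_chi(n, 2.5)
  fi <- simulate_fields(chi_int, mask)
  r_ext <- sqrt((g$X - 3)^2 + (g$Y - (n + 1) / 2)^2 + (g$Z - (n + 1) / 2)^2)
  chi_ext <- pmin(pmax(4.5 - r_ext, 0), 1) * 2
  f_ext <- simulate_fields(chi_ext, array(TRUE, dim = c(n, n, n)))
  tot <- fi$db_total$values + f_ext$db_total$values
  sh <- sharp(tot, mask)
  me <- sh$eroded_mask
  truth <- fi$db_local_true$values[me]
  truth <- truth - mean(truth)
  err <- sqrt(mean((sh$values[me] - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(err, 0.05)
  # insensitivity to adding any further harmonic field
  sh2 <- sharp(tot + 3 * f_ext$db_total$values, mask)
  expect_lt(max(abs(sh2$values - sh$values)), 0.05 * max(abs(sh$values)))
})

test_that("sharp is mask-local and validates inputs", {
  n <- 32
  g <- grid_radius(n)
  mask <- g$r <= 12
  x <- 0.1 * exp(-g$r^2 / 50)
  sh1 <- sharp(x, mask, erode_voxels = 2)
  y <- x
  y[!mask] <- y[!mask] + 5 # corrupt voxels outside the mask
  sh2 <- sharp(y, mask, erode_voxels = 2)
  expect_equal(sh1$values, sh2$values, tolerance = 1e-10)
  expect_error(sharp(array(NA_real_, dim = c(8, 8, 8)),
                     array(TRUE, dim = c(8, 8, 8))), "finite")
  expect_error(sharp(array(0, dim = c(8, 8, 8)),
                     array(TRUE, dim = c(8, 8, 8)), erode_voxels = 5),
               "empty|erod")
})
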