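gam <- gyromagnetic_ratio()
tes <- default_tes()

test_that("TE-weighted averaging: weights, identity and phi0 bias", {
  w <- tes / sum(tes)
  expect_equal(sum(w), 1)
  expect_equal(w[5], 24.6 / 69, tolerance = 1e-6)
  # pure field phase -> exact field
  b <- 1.7e-8
  ph <- array(0, dim = c(3, 3, 3, 5))
  for (i in 1:5) ph[, , , i] <- gam * b * tes[i]
  out <- te_weighted_average(ph, tes)
  expect_equal(out$values, array(b, dim = c(3, 3, 3)), tolerance = 1e-12)
  expect_equal(attr(out, "weights"), w)
  # constant phase offset biases by n * phi0 / (gamma * sum TE)
  phi0 <- 0.4
  out2 <- te_weighted_average(ph + phi0, tes)
  expect_equal(out2$values,
               array(b + 5 * phi0 / (gam * sum(tes)), dim = c(3, 3, 3)),
               tolerance = 1e-12)
  expect_error(te_weighted_average(ph, c(-1, tes[2:5])), "positive")
})

test_that("R2* fitting: noiseless recovery and degenerate cases", {
  n <- 4
  mag <- array(0, dim = c(n, n, n, 5))
  for (i in 1:5) mag[, , , i] <- 0.9 * exp(-tes[i] * 50) # T2* = 20 ms
  fit <- fit_r2star(mag, tes)
  expect_lt(max(abs(fit$r2star - 50) / 50), 1e-3)
  expect_lt(max(abs(fit$m0 - 0.9) / 0.9), 1e-3)
  # constant magnitude -> R2* = 0, M0 = the constant
  magc <- array(0.7, dim = c(2, 2, 2, 5))
  fitc <- fit_r2star(magc, tes)
  expect_equal(max(abs(fitc$r2star)), 0)
  expect_equal(fitc$m0, array(0.7, dim = c(2, 2, 2)), tolerance = 1e-8)
  # non-positive magnitudes are excluded and flagged
  magz <- magc
  magz[1, 1, 1, 3] <- 0
  fitz <- fit_r2star(magz, tes)
  expect_true(fitz$excluded[1, 1, 1])
  expect_equal(fitz$r2star[1, 1, 1], 0)
})

test_that("R2* log-linear initialisation equals closed-form OLS", {
  set.seed(12)
  mag <- array(exp(rnorm(8 * 5, -1, 0.2)), dim = c(2, 2, 2, 5))
  init <- fit_r2star(mag, tes, max_iter = 0) # no Gauss-Newton refinement
  M <- matrix(mag, 8, 5)
  for (v in 1:8) {
    ols <- stats::lm(log(M[v, ]) ~ tes)
    expect_equal(as.vector(init$r2star)[v],
                 max(-unname(stats::coef(ols)[2]), 0), tolerance = 1e-8)
    expect_equal(as.vector(init$m0)[v],
                 exp(unname(stats::coef(ols)[1])), tolerance = 1e-8)
  }
})

test_that("SNR-weighted averaging: weights and reductions", {
  # R2* = 0 reduces exactly to TE weighting
  set.seed(3)
  ph <- array(rnorm(27 * 5), dim = c(3, 3, 3, 5))
  r0 <- array(0, dim = c(3, 3, 3))
  expect_equal(snr_weighted_average(ph, tes, r0)$values,
               te_weighted_average(ph, tes)$values, tolerance = 1e-12)
  # weight value at R2* = 50 s^-1
  w <- tes * exp(-tes * 50)
  expect_equal((w / sum(w))[4], 0.2486, tolerance = 1e-3)
  # pure field phase -> field, independent of R2*
  b <- 2.3e-8
  for (i in 1:5) ph[, , , i] <- gam * b * tes[i]
  out <- snr_weighted_average(ph, tes, array(73, dim = c(3, 3, 3)))
  expect_equal(out$values, array(b, dim = c(3, 3, 3)), tolerance = 1e-12)
  wts <- attr(out, "weights")
  expect_equal(apply(wts, 1:3, sum), array(1, dim = c(3, 3, 3)),
               tolerance = 1e-12)
  expect_error(snr_weighted_average(ph, tes, r0 - 1), "non-negative")
})

test_that("susceptibility-weighted averaging: weights and flags", {
  n <- 3
  chi <- array(0, dim = c(n, n, n, 5))
  mag <- chi
  for (i in 1:5) {
    chi[, , , i] <- 0.11
    mag[, , , i] <- exp(-tes[i] * 50)
  }
  out <- susceptibility_weighted_average(chi, mag, tes)
  expect_equal(out$chi, array(0.11, dim = c(n, n, n)), tolerance = 1e-12)
  w <- (exp(-tes * 50))^2 * tes^2
  expect_equal(out$weights[1, 1, 1, 4], (w / sum(w))[4], tolerance = 1e-6)
  expect_equal((w / sum(w))[4], 0.2833, tolerance = 1e-3)
  expect_equal(apply(out$weights, 1:3, sum), array(1, dim = c(n, n, n)),
               tolerance = 1e-12)
  # all-zero magnitude voxel -> flagged, output 0
  mag[2, 2, 2, ] <- 0
  out2 <- susceptibility_weighted_average(chi, mag, tes)
  expect_true(out2$undefined[2, 2, 2])
  expect_equal(out2$chi[2, 2, 2], 0)
})

test_that("combination rules are convex and scale-equivariant", {
  set.seed(7)
  n <- 4
  ph <- array(rnorm(n^3 * 5), dim = c(n, n, n, 5))
  mag <- array(runif(n^3 * 5, 0.2, 1), dim = c(n, n, n, 5))
  r2 <- array(runif(n^3, 0, 100), dim = c(n, n, n))
  # convexity: per-voxel output of chi averaging within per-echo envelope
  sw <- susceptibility_weighted_average(ph, mag, tes)
  lo <- apply(ph, 1:3, min); hi <- apply(ph, 1:3, max)
  expect_true(all(sw$chi >= lo - 1e-12 & sw$chi <= hi + 1e-12))
  # magnitude scaling leaves Eq-10/Eq-13 style weights unchanged
  sw2 <- susceptibility_weighted_average(ph, 3.7 * mag, tes)
  expect_equal(sw2$weights, sw$weights, tolerance = 1e-12)
  snr1 <- snr_weighted_average(ph, tes, r2)
  expect_equal(apply(attr(snr1, "weights"), 1:3, sum),
               array(1, dim = c(n, n, n)), tolerance = 1e-12)
  # and the field combination is within the per-echo phase/TE envelope
  pv <- sapply(1:5, function(i) ph[, , , i] / (gam * tes[i]))
  expect_true(all(snr1$values >= apply(array(pv, c(n, n, n, 5)), 1:3, min) - 1e-12))
  expect_true(all(snr1$values <= apply(array(pv, c(n, n, n, 5)), 1:3, max) + 1e-12))
})
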