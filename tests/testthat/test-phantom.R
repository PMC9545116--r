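test_that("zero-SD tissue table gives piece-wise constant property maps", {
  tt <- default_tissue_table()
  tt$chi_sd_ppm[] <- 0
  tt$m0_sd[] <- 0
  tt$t2star_sd_ms[] <- 0
  spec <- phantom_spec(grid_shape = c(32, 32, 32), tissue_table = tt,
                       seed = 3)
  ph <- build_phantom(spec)
  for (i in seq_along(ph$name_map)) {
    sel <- ph$labels == i
    if (!any(sel)) next
    row <- tt[tt$region == ph$name_map[i], ]
    expect_equal(unique(ph$chi_true[sel]), row$chi_mean_ppm)
    expect_equal(unique(ph$m0_true[sel]), row$m0_mean)
    expect_equal(unique(ph$t2star_true[sel]), row$t2star_mean_ms)
  }
  expect_true(all(ph$m0_true[!ph$brain_mask] == 0))
})

test_that("sphere region voxel count matches its volume", {
  r <- 9
  spec <- phantom_spec(
    grid_shape = c(32, 32, 32),
    regions = list(list(region = "GM", type = "ellipsoid",
                        center = c(0.5, 0.5, 0.5),
                        semi_axes = rep(r / 32, 3))),
    seed = 1)
  ph <- build_phantom(spec)
  expect_lt(abs(sum(ph$labels == 1) - 4 / 3 * pi * r^3),
            0.05 * 4 / 3 * pi * r^3)
})

test_that("default phantom has the expected anatomy and protocol", {
  spec <- phantom_spec()
  regions <- vapply(spec$regions, `[[`, "", "region")
  for (nm in c("CN", "GP", "PU", "TH", "vein", "GM", "WM", "CSF"))
    expect_true(nm %in% regions)
  expect_equal(spec$echo_times_s, c(3, 8.4, 13.8, 19.2, 24.6) / 1000)
  expect_equal(spec$noise_sd, 0.07)
  expect_equal(spec$b0_tesla, 3)
})

test_that("field decomposition holds and is dipole-consistent", {
  spec <- sphere_phantom_spec(n = 32)
  ph <- build_phantom(spec)
  f <- simulate_fields(ph$chi_true, ph$brain_mask)
  resid <- f$db_total$values - f$db_background$values - f$db_local_true$values
  expect_lt(max(abs(resid)), 1e-18)

  # chi == 0 -> all fields zero
  f0 <- simulate_fields(array(0, dim = c(16, 16, 16)),
                        array(TRUE, dim = c(16, 16, 16)))
  expect_equal(max(abs(f0$db_total$values)), 0)
  expect_equal(max(abs(f0$db_local_true$values)), 0)

  # superposition / linearity of the forward model
  set.seed(5)
  c1 <- array(rnorm(16^3), dim = c(16, 16, 16))
  c2 <- array(rnorm(16^3), dim = c(16, 16, 16))
  m <- array(TRUE, dim = c(16, 16, 16))
  lhs <- simulate_fields(2 * c1 + c2, m)$db_total$values
  rhs <- 2 * simulate_fields(c1, m)$db_total$values +
    simulate_fields(c2, m)$db_total$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("sphere external field matches the analytic dipole solution", {
  n <- 64
  a <- 10
  chi <- sphere_chi(n, a)
  g <- grid_radius(n)
  mask <- g$r <= 28
  sim <- simulate_fields(chi, mask, b0_tesla = 3)$db_total$values
  ctr <- (n + 1) / 2
  ana <- array(0, dim = c(n, n, n))
  for (ox in c(-n, 0, n)) for (oy in c(-n, 0, n)) for (oz in c(-n, 0, n)) {
    dx <- g$X - ctr - ox; dy <- g$Y - ctr - oy; dz <- g$Z - ctr - oz
    rr2 <- dx^2 + dy^2 + dz^2
    ana <- ana + ifelse(rr2 > a^2,
                        (3e-6 * a^3 / 3) * (3 * dz^2 / rr2 - 1) / rr2^1.5, 0)
  }
  shell <- g$r >= 15 & g$r <= 20
  err <- sqrt(mean((sim[shell] - ana[shell])^2)) /
    sqrt(mean(ana[shell]^2))
  expect_lt(err, 0.01)
})

test_that("noise-free signal phase equals the field model exactly", {
  spec <- sphere_phantom_spec(n = 24, noise_sd = 0)
  st <- simulate_study(spec)
  gre <- st$gre[[1]]
  gam <- gyromagnetic_ratio()
  for (i in seq_along(spec$echo_times_s)) {
    expected <- gam * st$fields$db_total$values * spec$echo_times_s[i]
    sel <- st$phantom$m0_true > 0
    d <- qsmme:::wrap_phase(gre$phase[, , , i][sel] - expected[sel])
    expect_lt(max(abs(d)), 1e-10)
  }
  expect_equal(gre$magnitude[, , , 1][st$phantom$brain_mask],
               (st$phantom$m0_true *
                  exp(-spec$echo_times_s[1] * 1000 /
                        st$phantom$t2star_true))[st$phantom$brain_mask])
})

test_that("trivial acquisition gives unit magnitude and zero phase", {
  gt <- list(m0_true = array(1, dim = c(4, 4, 4)),
             t2star_true = array(1e12, dim = c(4, 4, 4)),
             phi0_true = array(0, dim = c(4, 4, 4)),
             db_total = array(0, dim = c(4, 4, 4)))
  spec <- phantom_spec(grid_shape = c(4, 4, 4), noise_sd = 0, seed = 1)
  gre <- simulate_gre(gt, spec, 1)[[1]]
  expect_lt(max(abs(gre$magnitude - 1)), 1e-9)
  expect_lt(max(abs(gre$phase)), 1e-9)
})

test_that("repeats share ground truth but use independent noise", {
  spec <- sphere_phantom_spec(n = 16, noise_sd = 0.07, seed = 21)
  st <- simulate_study(spec, n_repeats = 2)
  g1 <- st$gre[[1]]; g2 <- st$gre[[2]]
  expect_false(identical(g1$phase, g2$phase))
  # same seed -> bit-identical regeneration
  st2 <- simulate_study(spec, n_repeats = 2)
  expect_identical(g1$magnitude, st2$gre[[1]]$magnitude)
  expect_identical(g2$phase, st2$gre[[2]]$phase)
  # noiseless repeats are bit-identical
  spec0 <- sphere_phantom_spec(n = 16, noise_sd = 0, seed = 21)
  st0 <- simulate_study(spec0, n_repeats = 2)
  expect_identical(st0$gre[[1]]$magnitude, st0$gre[[2]]$magnitude)
})

test_that("measured phase noise matches 1/SNR at high SNR", {
  nmc <- 10000
  gt <- list(m0_true = array(1, dim = c(nmc, 1, 1)),
             t2star_true = array(1e12, dim = c(nmc, 1, 1)),
             phi0_true = array(0, dim = c(nmc, 1, 1)),
             db_total = array(0, dim = c(nmc, 1, 1)))
  spec <- phantom_spec(grid_shape = c(nmc, 1, 1), noise_sd = 0.07,
                       seed = 9, echo_times_s = 0.003)
  gre <- simulate_gre(gt, spec, 1)[[1]]
  expect_equal(stats::sd(gre$phase[, , , 1]), 0.07, tolerance = 0.03)
})

test_that("mask erosion follows the cubic structuring element", {
  cube <- array(FALSE, dim = c(15, 15, 15))
  cube[3:13, 3:13, 3:13] <- TRUE # 11^3 block
  expect_identical(erode_mask(cube, 0), cube)
  e5 <- erode_mask(cube, 5)
  expect_equal(sum(e5), 1)
  expect_true(e5[8, 8, 8])
  # brute-force reference at radius 2
  ref <- array(FALSE, dim = c(15, 15, 15))
  for (i in 5:11) for (j in 5:11) for (k in 5:11) ref[i, j, k] <- TRUE
  expect_identical(erode_mask(cube, 2), ref)
  expect_error(erode_mask(cube, 6), "empty")
})

test_that("phantom_from_labels resamples and samples properties", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[5:16, 5:16, 5:16] <- 1L
  lab[9:12, 9:12, 9:12] <- 2L
  ph <- phantom_from_labels(lab, name_map = c("WM", "GP"),
                            target_shape = c(10, 10, 10),
                            spec_args = list(seed = 4))
  expect_equal(dim(ph$labels), c(10, 10, 10))
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L, 2L))
  tt <- default_tissue_table()
  gp <- ph$chi_true[ph$labels == 2]
  expect_equal(mean(gp), tt$chi_mean_ppm[tt$region == "GP"],
               tolerance = 0.1)
})
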