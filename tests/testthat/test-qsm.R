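test_that("Laplacian unwrapping handles constant, wrap-free and ramp phases", {
  g <- small_geometry(32)
  dims <- g$grid_shape
  mask <- array(TRUE, dim = dims)

  mk_series <- function(ph_true) {
    ne <- 3L
    mag <- array(1, dim = c(dims, ne))
    ph <- array(0, dim = c(dims, ne))
    for (e in 1:ne) ph[, , , e] <- dgmiron:::wrap_phase(ph_true)
    as_echo_series(mag, ph, small_geometry(32, echoes = c(1, 2, 3)))
  }

  # constant phase: unchanged up to a multiple of 2*pi
  s_const <- mk_series(array(0.5, dim = dims))
  uw <- unwrap_phase(s_const, mask)[, , , 1]
  expect_lt(max(abs(uw - uw[1, 1, 1])), 1e-9)
  expect_equal((uw[1, 1, 1] - 0.5) %% (2 * pi), 0, tolerance = 1e-9)

  # already-unwrapped smooth phase within (-pi, pi]: identity up to constant
  smooth <- array(0, dim = dims)
  co <- dgmiron:::voxel_coords(g)
  smooth <- outer(outer(sin(co[[1]] / 30), cos(co[[2]] / 40), `+`),
                  0 * co[[3]], `+`) * 0.8
  dim(smooth) <- dims
  s_sm <- mk_series(smooth)
  uw_sm <- unwrap_phase(s_sm, mask)[, , , 1]
  expect_lt(max(abs(uw_sm - smooth)), 1e-6)

  # linear ramp spanning ~6*pi across the grid
  n <- dims[1]
  ramp_1d <- 2 * pi * 3 * (0:(n - 1)) / n
  ramp <- array(rep(ramp_1d, times = n * n), dim = dims)
  s_ramp <- mk_series(ramp)
  uw_r <- unwrap_phase(s_ramp, mask)[, , , 1]
  dev <- uw_r - ramp
  dev <- dev - 2 * pi * round(stats::median(dev) / (2 * pi))
  expect_lt(max(abs(dev)), 0.01)

  expect_error(unwrap_phase(s_const, array(FALSE, dim = dims)), "mask")
})

test_that("field fitting is exact on noiseless data and validates inputs", {
  g <- small_geometry(16)
  s25 <- uniform_series(g, freq_hz = 25)
  te_s <- g$echo_times / 1000
  uw <- array(0, dim = dim(s25$phase))
  for (e in seq_along(te_s)) uw[, , , e] <- 2 * pi * 25 * te_s[e]
  fm <- fit_field(uw, s25)
  expect_equal(max(abs(fm$frequency - 25)), 0, tolerance = 1e-9)
  expect_lt(max(fm$residual), 1e-9)

  s0 <- uniform_series(g, freq_hz = 0)
  fm0 <- fit_field(s0$phase, s0)
  expect_equal(max(abs(fm0$frequency)), 0)
  expect_equal(max(fm0$residual), 0)

  g1 <- small_geometry(8, echoes = 1.68)
  s1 <- uniform_series(g1)
  expect_error(fit_field(s1$phase, s1), "2 echoes")
})

test_that("reliability mask drops only corrupted voxels", {
  g <- small_geometry(16)
  mask <- array(TRUE, dim = g$grid_shape)
  s <- uniform_series(g, freq_hz = 5)
  fm <- fit_field(unwrap_phase(s, mask), s, mask)
  cfg <- recon_config()
  expect_true(all(reliability_mask(fm, cfg)))
  cfg_inf <- recon_config(residual_threshold = Inf)
  expect_identical(reliability_mask(fm, cfg_inf), fm$mask)

  # corrupt one echo at one voxel by 3 rad
  s_bad <- s
  s_bad$phase[8, 8, 8, 5] <- dgmiron:::wrap_phase(s_bad$phase[8, 8, 8, 5] + 3)
  uw <- unwrap_phase(s_bad, mask)
  fm_bad <- fit_field(uw, s_bad, mask)
  rel <- reliability_mask(fm_bad, cfg)
  expect_false(rel[8, 8, 8])
  away <- rel
  away[6:10, 6:10, 6:10] <- TRUE  # ignore the corrupted neighbourhood
  expect_true(all(away))
})

test_that("V-SHARP removes external fields and preserves interior sources", {
  g <- small_geometry(64)
  ph <- make_phantom(g, default_roi_spec()[0, ])
  mask <- ph$brain_mask
  co <- dgmiron:::voxel_coords(g)
  cfg <- recon_config()

  # zero field stays zero
  z <- as_field_map(array(0, dim = g$grid_shape), mask)
  loc0 <- remove_background(z, mask, cfg, g)
  expect_equal(max(abs(loc0$frequency)), 0)

  # field from a strong source outside the brain: suppressed below 5% RMS
  chi_ext <- array(0, dim = g$grid_shape)
  r2e <- outer(outer((co[[1]] + 36.5)^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  dim(r2e) <- g$grid_shape
  chi_ext[r2e <= 1.8^2] <- 20000
  expect_true(all(!(chi_ext > 0 & mask)))
  f_ext <- forward_field(list(chi = chi_ext, brain_mask = mask), g)
  loc_e <- remove_background(as_field_map(f_ext$frequency, mask), mask, cfg, g)
  ratio <- sqrt(mean(loc_e$frequency[loc_e$mask]^2)) /
    sqrt(mean(f_ext$frequency[loc_e$mask]^2))
  expect_lt(ratio, 0.05)

  # field from an interior ellipsoid: ROI-mean preserved above 80%
  chi_int <- array(0, dim = g$grid_shape)
  ell <- outer(outer((co[[1]] / 4)^2, (co[[2]] / 8)^2, `+`), (co[[3]] / 5)^2, `+`)
  dim(ell) <- g$grid_shape
  chi_int[ell <= 1] <- 100
  f_int <- forward_field(list(chi = chi_int, brain_mask = mask), g)
  loc_i <- remove_background(as_field_map(f_int$frequency, mask), mask, cfg, g)
  m <- (ell <= 1) & loc_i$mask
  expect_gt(mean(loc_i$frequency[m]) / mean(f_int$frequency[m]), 0.8)

  expect_error(remove_background(z, array(FALSE, dim = g$grid_shape), cfg, g),
               "mask")
})

test_that("TKD inversion: trivial cases, linearity and threshold validation", {
  g <- small_geometry(24)
  dims <- g$grid_shape
  mask <- array(TRUE, dim = dims)
  cfg <- recon_config()
  z <- as_field_map(array(0, dim = dims), mask)
  expect_equal(max(abs(invert_dipole(z, g, cfg)$chi)), 0)

  set.seed(11)
  f <- array(stats::rnorm(prod(dims)), dim = dims)
  q1 <- invert_dipole(as_field_map(f, mask), g, cfg)
  q2 <- invert_dipole(as_field_map(2 * f, mask), g, cfg)
  expect_equal(q2$chi, 2 * q1$chi, tolerance = 1e-12)

  expect_error(invert_dipole(z, g, recon_config(tkd_threshold = 1.2)),
               "tkd_threshold")
})

test_that("uncorrected TKD inverts the forward model on |D| >= delta exactly", {
  g <- small_geometry(24)
  dims <- g$grid_shape
  mask <- array(TRUE, dim = dims)
  set.seed(5)
  chi <- array(0, dim = dims)
  co <- dgmiron:::voxel_coords(g)
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  dim(r2) <- dims
  core <- r2 <= 10^2
  chi[core] <- stats::rnorm(sum(core), sd = 20)
  # circular convolution so forward and inverse share one k-space grid
  f <- forward_field(list(chi = chi, brain_mask = mask), g, pad = FALSE)
  cfg <- recon_config(tkd_threshold = 0.15, tkd_correction = FALSE)
  rec <- invert_dipole(as_field_map(f$frequency, mask), g, cfg)
  D <- dipole_kernel(g)$values
  K_true <- fft(chi)
  K_rec <- fft(rec$chi)
  keep <- abs(D) >= 0.15
  keep[1, 1, 1] <- FALSE
  # relative spectral error on well-conditioned components
  err <- max(abs(K_rec[keep] - K_true[keep])) / max(abs(K_true[keep]))
  expect_lt(err, 1e-10)
})

test_that("referencing zeroes the brain mean, is idempotent, and absorbs field offsets", {
  g <- small_geometry(24)
  dims <- g$grid_shape
  mask_all <- array(TRUE, dim = dims)
  set.seed(7)
  chi <- array(stats::rnorm(prod(dims)), dim = dims)
  m <- as_chi_map(chi, mask_all)
  r1 <- reference_qsm(m, reference = "brain_mean")
  expect_lt(abs(mean(r1$chi[mask_all])), 1e-6)
  r2 <- reference_qsm(r1, reference = "brain_mean")
  expect_equal(r1$chi, r2$chi, tolerance = 1e-12)
  expect_identical(reference_qsm(m, reference = "none"), m)

  # a constant local-field offset only changes the k = 0 term, so the
  # referenced susceptibility is invariant
  f <- array(stats::rnorm(prod(dims)), dim = dims)
  cfg <- recon_config()
  qa <- reference_qsm(invert_dipole(as_field_map(f, mask_all), g, cfg),
                      reference = "brain_mean")
  qb <- reference_qsm(invert_dipole(as_field_map(f + 3.7, mask_all), g, cfg),
                      reference = "brain_mean")
  expect_equal(qa$chi, qb$chi, tolerance = 1e-8)
})
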