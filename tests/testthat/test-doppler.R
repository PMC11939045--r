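test_that("SVD clutter filter removes static signal and is a projection", {
  # strictly static series: rank 1 in slow time, fully captured by the
  # first mode
  set.seed(1)
  dims <- c(5, 5, 4); nt <- 80
  amp <- complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims)))
  iq <- iq_volume_series(array(rep(amp, nt), c(dims, nt)),
                         voxel_grid(1:5 * 1e-4, 1:5 * 1e-4, 1:4 * 1e-4),
                         500)
  f <- svd_clutter_filter(iq, clutter_filter_spec(0.15, 10))
  expect_lt(sum(Mod(f$data)^2), 1e-10 * sum(Mod(iq$data)^2))

  # the in vivo rule on 200 frames removes the first 30 modes
  iq2 <- synth_iq_series(dims = c(4, 4, 4), n_slow = 200, vz = 1e-3,
                         noise_sd = 0.2)
  f2 <- svd_clutter_filter(iq2)
  expect_equal(length(attr(f2, "modes_removed")$low), 30)
  expect_equal(length(attr(f2, "modes_removed")$high), 50)
  # the retained-subspace projector is idempotent
  f3 <- project_clutter_basis(f2, attr(f2, "basis"))
  expect_equal(f3$data, f2$data, tolerance = 1e-8)

  short <- synth_iq_series(n_slow = 40)
  expect_error(svd_clutter_filter(short), "too short")
})

test_that("power Doppler is quadratic in amplitude and phase invariant", {
  iq <- synth_iq_series(n_slow = 50, vz = 1.5e-3, noise_sd = 0.05)
  pd1 <- power_doppler(iq)
  iq2 <- iq; iq2$data <- 3 * iq$data
  expect_equal(power_doppler(iq2)$values, 9 * pd1$values, tolerance = 1e-12)
  iq3 <- iq; iq3$data <- iq$data * exp(1i * 1.2)
  expect_equal(power_doppler(iq3)$values, pd1$values, tolerance = 1e-12)
  iq$data <- iq$data * 0
  expect_true(all(power_doppler(iq)$values == 0))
})

test_that("signed power Doppler encodes flow direction and preserves magnitude", {
  msk <- array(TRUE, c(6, 6, 6))
  toward <- synth_iq_series(vz = 2e-3, moving_mask = msk, n_slow = 60)
  sp <- signed_power_doppler(toward)
  expect_true(all(sp$values > 0)) # toward the array: positive
  away <- toward; away$data <- Conj(toward$data)
  sn <- signed_power_doppler(away)
  expect_true(all(sn$values < 0))
  expect_equal(abs(sn$values), abs(sp$values), tolerance = 1e-12)
})

test_that("flow voxels dominate power Doppler after clutter filtering", {
  # moving voxels + static clutter + noise
  dims <- c(6, 6, 6)
  mv <- array(FALSE, dims); mv[3:4, 3:4, 3:4] <- TRUE
  set.seed(5)
  iq <- synth_iq_series(dims = dims, n_slow = 100, vz = 3e-3,
                        moving_mask = mv, noise_sd = 0.05, seed = 5)
  # add strong static clutter everywhere
  clut <- complex(real = rnorm(prod(dims), 0, 10),
                  imaginary = rnorm(prod(dims), 0, 10))
  iq$data <- iq$data + array(rep(clut, 100), c(dims, 100))
  # the static clutter is exactly rank 1 here
  f <- svd_clutter_filter(iq, clutter_filter_spec(high_count = 10,
                                                  low_count = 1))
  pd <- power_doppler(f)
  expect_gt(mean(pd$values[mv]), 20 * mean(pd$values[!mv]))
})

test_that("skin-surface fitting recovers synthetic interfaces and masks above them", {
  g <- voxel_grid(seq_len(12) * 2e-4, seq_len(12) * 2e-4,
                  seq(2e-4, 4e-3, by = 1e-4))
  z0 <- 1.5e-3
  v <- array(10^(-60 / 20), c(12, 12, length(g$z)))
  v[, , g$z >= z0] <- 1 # bright tissue below a flat interface
  bm <- rcaflow:::new_volume(20 * log10(v), g)
  fit <- fit_skin_surface(bm, poly_order = 2)
  expect_true(all(abs(fit$surface - z0) < 1.5e-4))
  expect_true(all(!fit$mask[, , g$z < z0 - 1e-4]))
  expect_true(all(fit$mask[, , g$z > z0 + 1e-4]))
  # order 0 on a tilted interface gives the mean plane
  vt <- array(10^(-60 / 20), dim(v))
  zint <- 1e-3 + (seq_len(12) - 1) * 5e-5
  for (ix in 1:12) vt[ix, , g$z >= zint[ix]] <- 1
  bt <- rcaflow:::new_volume(20 * log10(vt), g)
  f0 <- fit_skin_surface(bt, poly_order = 0)
  expect_equal(mean(f0$surface), mean(f0$points$z), tolerance = 1e-6)
  expect_lt(abs(mean(f0$surface) - mean(zint)), 1.5e-4)
  # masked voxels contribute nothing downstream
  iq <- synth_iq_series(dims = c(12, 12, length(g$z)), n_slow = 30)
  masked <- apply_skin_mask(iq, fit$mask)
  expect_true(all(Mod(masked$data[, , g$z < z0 - 1e-4, ]) == 0))
})

test_that("spectral Doppler places ridges at the programmed velocity and aliases past Nyquist", {
  fr <- 500; f0 <- 9.02e6; c <- 1480
  v_true <- 5e-3
  iq <- synth_iq_series(dims = c(5, 5, 5), n_slow = 120, framerate_hz = fr,
                        vz = v_true, noise_sd = 0.02, seed = 2)
  sp <- spectral_doppler(iq, c(3, 3, 3), c = c)
  ridge <- sp$velocity[apply(sp$magnitude, 2, which.max)]
  dv <- c * fr / (2 * f0) / sp$window # one bin
  expect_true(all(abs(ridge - v_true) <= dv + 1e-9))

  v_nyq <- c * fr / (4 * f0)
  iq2 <- synth_iq_series(dims = c(5, 5, 5), n_slow = 120, framerate_hz = fr,
                         vz = 1.5 * v_nyq, seed = 3)
  sp2 <- spectral_doppler(iq2, c(3, 3, 3), c = c)
  ridge2 <- sp2$velocity[apply(sp2$magnitude, 2, which.max)]
  expect_true(all(ridge2 < 0)) # wrapped to negative velocities
  expect_true(all(abs(ridge2 + 0.5 * v_nyq) <= dv + 1e-9))
  expect_error(spectral_doppler(iq, c(1, 1, 1)), "outside")

  # velocity axis spans the slow-time Nyquist interval
  expect_equal(max(sp$velocity), c * (fr / 2) / (2 * f0),
               tolerance = 2 / sp$window)
})

test_that("resistive index follows its definition and the generator round-trips", {
  fr <- 100
  tt <- seq(0, 3, by = 1 / fr)
  v <- 5 + 5 * pmax(sin(2 * pi * tt), 0) # peak 10, end-diastolic 5
  expect_equal(resistive_index(v, fr), 0.5, tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(resistive_index(rep(3, 200), fr), 0)
  expect_error(resistive_index(-v, fr), "non-positive")

  wf <- pulse_waveform_fn(hr_bpm = 70, ri = 0.57)
  vt <- 0.01 * wf$w(seq(0, 4, by = 1 / fr))
  expect_equal(resistive_index(vt, fr), 0.57, tolerance = 0.02,
               ignore_attr = TRUE)
})
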