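test_that("demodulation preserves envelopes and in-band energy", {
  ph <- make_bead_phantom(2e-3)
  sch <- build_scheme("SPW", small_array(16), prf_hz = 10e3,
                      angle_span_deg = c(0, 0), angle_step_deg = 1)
  cd <- simulate_ensemble(ph, sch, pulse_spec(), depth_max = 3e-3)
  bb <- demodulate(cd)
  rf <- cd$samples[, 8, 1, 1]
  env_ref <- Mod(rcaflow:::analytic_signal(rf))
  env_bb <- Mod(bb$samples[, 8, 1, 1])
  expect_lt(abs(which.max(env_ref) - which.max(env_bb)), 2)
  # energy preserved within 1% (baseband holds half the RF amplitude)
  expect_equal(2 * sum(env_bb^2), sum(rf^2), tolerance = 0.01)
  expect_error(demodulate(bb), "already baseband")
})

test_that("a pure tone demodulates to constant magnitude", {
  sch <- build_scheme("SA", small_array(4), prf_hz = 10e3)
  t <- (0:499) / 50e6
  tone <- sin(2 * pi * 9.02e6 * t)
  x <- array(rep(tone, 4 * 4), c(500, 4, 4, 1))
  cd <- rcaflow:::new_channel_data(x, 50e6, 10e3, sch, "rf", 0,
                                   pulse = pulse_spec(fs = 50e6))
  bb <- demodulate(cd, f0 = 9.02e6)
  mid <- Mod(bb$samples[100:400, 1, 1, 1])
  expect_lt(stats::sd(mid) / mean(mid), 1e-3)
})

test_that("delay-and-sum focuses a point target at its true position", {
  med <- medium_spec()
  arr <- array_spec()
  ph <- make_bead_phantom(3e-3)
  sch <- build_scheme("SPW", arr, prf_hz = 10e3, angle_span_deg = c(0, 0),
                      angle_step_deg = 1)
  cd <- simulate_ensemble(ph, sch, domain = "baseband", depth_max = 4e-3)
  grid <- voxel_grid(seq(-6e-4, 6e-4, by = 1.5e-4),
                     seq(-6e-4, 6e-4, by = 1.5e-4),
                     seq(2.6e-3, 3.4e-3, by = 5e-5))
  vol <- das_rca(cd, 1, grid, med)
  pk <- which(Mod(vol) == max(Mod(vol)), arr.ind = TRUE)[1, ]
  # a single broadside transmit focuses in x (receive) and z (time); the
  # transmit axis stays unfocused until events are compounded
  expect_equal(grid$x[pk[1]], 0, tolerance = 1.6e-4)
  expect_equal(grid$z[pk[3]], 3e-3, tolerance = 6e-5)
  yprof <- Mod(vol[pk[1], , pk[3]])
  expect_gt(min(yprof) / max(yprof), 0.5) # near-flat along the tx axis

  # translation equivariance along the receive axis (one pitch in x)
  ph2 <- rcaflow:::new_phantom(matrix(c(150e-6, 0, 3e-3), 1, 3), 1, "bead",
                               med, 0L)
  cd2 <- simulate_ensemble(ph2, sch, domain = "baseband", depth_max = 4e-3)
  vol2 <- das_rca(cd2, 1, grid, med)
  pk2 <- which(Mod(vol2) == max(Mod(vol2)), arr.ind = TRUE)[1, ]
  expect_equal(grid$x[pk2[1]] - grid$x[pk[1]], 150e-6, tolerance = 1e-12)
  expect_equal(pk2[2:3], pk[2:3])
})

test_that("tighter receive f-numbers broaden the receive-axis beam", {
  med <- medium_spec()
  ph <- make_bead_phantom(3e-3)
  sch <- build_scheme("SPW", array_spec(), prf_hz = 10e3,
                      angle_span_deg = c(0, 0), angle_step_deg = 1)
  cd <- simulate_ensemble(ph, sch, domain = "baseband", depth_max = 4e-3,
                          tx_model = "plane")
  grid <- voxel_grid(seq(-8e-4, 8e-4, by = 4e-5), 0,
                     seq(2.9e-3, 3.1e-3, by = 5e-5))
  w <- vapply(c(0, 1, 2), function(fn) {
    vol <- das_rca(cd, 1, grid, med, rx_fnumber = fn)
    profile_fwhm(intensity_volume(vol, grid = grid), "x")
  }, 0)
  expect_lt(w[1], w[2]) # full aperture narrower than f/1
  expect_lt(w[2], w[3]) # f/1 narrower than f/2
})

test_that("orthogonal compounding is x/y symmetric and HSA matches SA voxel-wise", {
  med <- medium_spec()
  arr <- array_spec()
  ph <- make_bead_phantom(3e-3)
  grid <- voxel_grid(seq(-6e-4, 6e-4, by = 1.2e-4),
                     seq(-6e-4, 6e-4, by = 1.2e-4),
                     seq(2.8e-3, 3.2e-3, by = 5e-5))
  opw <- scheme_preset("OPW8+8", arr)
  cdo <- simulate_ensemble(ph, opw, domain = "baseband", depth_max = 4e-3)
  iqo <- beamform_series(cdo, grid, med)
  v <- Mod(iqo$data[, , , 1])
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-6)

  sa <- build_scheme("SA", arr, prf_hz = 20e3)
  cds <- simulate_ensemble(ph, sa, domain = "baseband", depth_max = 4e-3)
  iqs <- beamform_series(cds, grid, med)
  hsa <- build_scheme("HSA", arr, prf_hz = 20e3)
  cdh <- simulate_ensemble(ph, hsa, domain = "baseband", depth_max = 4e-3)
  expect_error(beamform_series(cdh, grid, med), "decode")
  iqh <- beamform_series(hadamard_decode(cdh), grid, med)
  expect_lt(max(Mod(iqh$data - iqs$data)) / max(Mod(iqs$data)), 1e-8)

  # at least half the image energy concentrates within 3x3x3 of the target
  # for the well-compounded schemes (the 8+8 compound beam is too wide)
  opw16 <- scheme_preset("OPW16+16", arr)
  cd16 <- simulate_ensemble(ph, opw16, domain = "baseband",
                            depth_max = 4e-3)
  iq16 <- beamform_series(cd16, grid, med)
  for (iq in list(iq16, iqs)) {
    iv <- Mod(iq$data[, , , 1])^2
    pk <- which(iv == max(iv), arr.ind = TRUE)[1, ]
    box <- iv[pmax(pk[1] - 1, 1):pmin(pk[1] + 1, dim(iv)[1]),
              pmax(pk[2] - 1, 1):pmin(pk[2] + 1, dim(iv)[2]),
              pmax(pk[3] - 1, 1):pmin(pk[3] + 1, dim(iv)[3])]
    expect_gt(sum(box) / sum(iv), 0.5)
  }
})

test_that("XDoppler self-correlation equals power Doppler and rejects noise", {
  iq <- synth_iq_series(n_slow = 60, vz = 2e-3, noise_sd = 0.1, seed = 2)
  xd <- xdoppler_power(iq, iq)
  pd <- power_doppler(iq)
  expect_equal(xd$values, pd$values, tolerance = 1e-12)

  na <- synth_iq_series(dims = c(5, 5, 4), n_slow = 400, vz = 0, seed = 3)
  nb <- synth_iq_series(dims = c(5, 5, 4), n_slow = 400, vz = 0, seed = 4)
  na$data <- array(complex(real = rnorm(length(na$data)),
                           imaginary = rnorm(length(na$data))), dim(na$data))
  nb$data <- array(complex(real = rnorm(length(nb$data)),
                           imaginary = rnorm(length(nb$data))), dim(nb$data))
  xd2 <- xdoppler_power(na, nb)
  pda <- power_doppler(na)
  # cross terms average out: well below the noise power Doppler
  expect_lt(mean(xd2$values) / mean(pda$values), 3 / sqrt(400))
  nb$data <- nb$data[, , , 1:100]
  expect_error(xdoppler_power(na, nb), "mismatch")
})

test_that("B-mode normalizes to 0 dB and is scale invariant", {
  v <- array(complex(real = rnorm(27), imaginary = rnorm(27)), c(3, 3, 3))
  g <- voxel_grid(1:3 * 1e-4, 1:3 * 1e-4, 1:3 * 1e-4)
  b1 <- bmode(v, g)
  expect_equal(max(b1$values), 0)
  b2 <- bmode(10 * v, g)
  expect_equal(b1$values, b2$values, tolerance = 1e-12)
  expect_error(bmode(v * 0, g), "all-zero")
})
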