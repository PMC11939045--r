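test_that("bead phantom places one static scatterer on axis", {
  for (d in c(4.8e-3, 6e-3)) {
    ph <- make_bead_phantom(d)
    expect_equal(nrow(ph$positions), 1)
    expect_equal(as.numeric(ph$positions), c(0, 0, d))
    expect_equal(ph$labels, "bead")
  }
})

test_that("zero-amplitude scatterers produce identically zero echoes", {
  ph <- make_bead_phantom(2e-3, amplitude = 0)
  cd <- simulate_ensemble(ph, build_scheme("SA", small_array(8)),
                          fast_pulse(), depth_max = 3e-3)
  expect_true(all(cd$samples == 0))
})

test_that("flow-tube scatterers move at the prescribed speed and are reproducible", {
  ph <- make_flow_tube(speed = 0.01, seed = 5)
  v <- rcaflow:::instantaneous_velocity(ph, 0)
  blood <- ph$labels == "blood"
  expect_true(all(abs(sqrt(rowSums(v[blood, , drop = FALSE]^2)) - 0.01)
                  < 1e-12))
  expect_true(all(v[!blood, ] == 0))
  ph2 <- make_flow_tube(speed = 0.01, seed = 5)
  expect_identical(ph$positions, ph2$positions)
  ph3 <- make_flow_tube(speed = 0.01, seed = 6)
  expect_false(identical(ph$positions, ph3$positions))
  expect_error(make_flow_tube(depth = 20e-3), "outside the field of view")
})

test_that("advancing a phantom integrates displacement and recycles at inlets", {
  ph <- make_flow_tube(speed = 0.01, seed = 2)
  # one OPW32+32 frame at 312.5 Hz moves blood by 32 um
  adv <- advance_phantom(ph, 1 / 312.5)
  blood <- ph$labels == "blood"
  len <- ph$flow$vessels[[1]]$length
  dx <- adv$positions[blood, 1] - ph$positions[blood, 1]
  expect_true(all(abs(dx - 3.2e-5) < 1e-9 |
                    abs(dx - 3.2e-5 + len) < 1e-9)) # moved or recycled

  # static phantom unchanged
  st <- make_flow_tube(speed = 0, seed = 2)
  expect_equal(advance_phantom(st, 0.5)$positions, st$positions)

  # recycling keeps every scatterer inside its segment at all times
  ves <- ph$flow$vessels[[1]]
  for (t in seq(0, 400 / 312.5, length.out = 9)) {
    p <- advance_phantom(ph, t)$positions[blood, , drop = FALSE]
    s <- (p - matrix(rep(ves$p0, each = sum(blood)), sum(blood), 3)) %*%
      ves$axis
    expect_true(all(s >= -1e-12 & s <= ves$length + 1e-12))
    expect_equal(nrow(p), sum(blood))
  }
})

test_that("pulsatile waveform hits its resistive-index target with unit mean", {
  for (ri in c(0.4, 0.57, 0.8)) {
    wf <- pulse_waveform_fn(hr_bpm = 70, ri = ri)
    tt <- seq(0, wf$period, length.out = 4000)
    w <- wf$w(tt)
    expect_equal((max(w) - min(w)) / max(w), ri, tolerance = 0.01)
    expect_equal(mean(w), 1, tolerance = 0.01)
  }
})

test_that("vascular tree emulates plexus-plus-artery geometry with shared pulsatility", {
  ph <- make_vascular_tree(seed = 4)
  expect_true(all(c("blood", "tissue") %in% ph$labels))
  depths <- vapply(ph$flow$vessels, function(v) v$p0[3], 0)
  expect_true(any(abs(depths - 4e-3) < 1e-4)) # deep artery
  expect_true(any(depths < 1.5e-3))           # plexus
  expect_equal(ph$waveform$ri, 0.57)

  # explicit segments degenerate to a deterministic two-tube fixture
  two <- make_vascular_tree(list(segments = list(
    list(p0 = c(-1e-3, -167e-6, 1e-3), p1 = c(1e-3, -167e-6, 1e-3),
         diameter = 150e-6, v_mean = 5e-3),
    list(p0 = c(-1e-3, 167e-6, 1e-3), p1 = c(1e-3, 167e-6, 1e-3),
         diameter = 150e-6, v_mean = 5e-3)), pulsatile = FALSE,
    tissue_density = 0), seed = 1)
  ys <- vapply(two$flow$vessels, function(v) v$p0[2], 0)
  expect_equal(diff(sort(ys)), 334e-6)
  expect_error(make_vascular_tree(list(segments = list(
    list(p0 = c(0, 0, 1e-4), p1 = c(1e-3, 0, 1e-4), diameter = 1e-3,
         v_mean = 1e-3)))), "outside the field of view")
})

test_that("synthetic ECG trains have the requested rate, jitter and determinism", {
  e <- make_ecg_trace(hr_bpm = 60, duration = 10, hrv_sd_bpm = 0, seed = 1)
  expect_equal(diff(e$r_peak_times), rep(1, length(e$r_peak_times) - 1))
  e2 <- make_ecg_trace(hr_bpm = 69.7, duration = 110, hrv_sd_bpm = 3,
                       seed = 2)
  expect_equal(length(e2$r_peak_times), 69.7 * 110 / 60, tolerance = 0.05)
  expect_identical(make_ecg_trace(69.7, 110, 3, seed = 2)$r_peak_times,
                   e2$r_peak_times)
  expect_true(all(diff(e2$r_peak_times) > 0))
})

test_that("stimulus PBV generator is causal with the documented plateau", {
  gen <- make_stimulus_pbv(noise_sd = 0, seed = 1)
  base <- gen$time < 30
  expect_true(all(abs(gen$truth[base] - 1) < 1e-12))
  # plateau over baseline reaches the +113% default
  expect_equal(gen$truth[length(gen$truth)] - 1, 1.13, tolerance = 0.01)
  # cold transient dips below baseline between the stimuli
  mid <- gen$time >= 30 & gen$time < 60
  expect_true(min(gen$truth[mid]) < 0.9)
  g2 <- make_stimulus_pbv(noise_sd = 0.05, n_voxels = 3, seed = 7)
  expect_identical(dim(g2$pbv), c(3L, length(g2$time)))
  expect_identical(make_stimulus_pbv(noise_sd = 0.05, n_voxels = 3,
                                     seed = 7)$pbv, g2$pbv)
})
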