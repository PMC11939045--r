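test_that("Kasai estimator recovers imposed phase shifts exactly", {
  fr <- 1000; f0 <- 9.02e6; c <- 1480
  dphi <- pi / 2
  vz <- c * fr * dphi / (4 * pi * f0)
  iq <- synth_iq_series(dims = c(5, 5, 5), n_slow = 40, framerate_hz = fr,
                        vz = vz, f0 = f0, c = c)
  ks <- kasai_phase_shift(iq, c = c, kernel = c(0, 0, 0, 0))
  expect_lt(max(abs(ks$velocity - vz)) / vz, 1e-10)
  # the quarter-turn phase shift at 1 kHz corresponds to ~20.5 mm/s
  expect_equal(vz, 0.020510, tolerance = 1e-4)
  expect_equal(dim(ks$velocity)[4], 39) # n_slow - 1

  # beyond an eighth of a wavelength per frame the estimate wraps
  v_wrap <- 1.5 * c * fr / (4 * f0)
  iqw <- synth_iq_series(dims = c(4, 4, 4), n_slow = 10, framerate_hz = fr,
                         vz = v_wrap, f0 = f0, c = c)
  kw <- kasai_phase_shift(iqw, c = c, kernel = c(0, 0, 0, 0))
  expect_lt(max(kw$velocity), 0) # aliased to negative velocity

  filt <- iq; filt$filtered <- TRUE
  expect_warning(kasai_phase_shift(filt, c = c), "clutter-filtered")
})

make_pulse_train <- function(times, peaks, sigma = 0.0276, delay = 0) {
  out <- numeric(length(times))
  for (p in peaks) out <- out + exp(-(times - p - delay)^2 / (2 * sigma^2))
  out
}

test_that("SVD + ICA separates the cardiac pulse from global drift artifacts", {
  fr <- 250
  tt <- seq(0, 20 - 1 / fr, by = 1 / fr)
  ecg <- make_ecg_trace(hr_bpm = 72, duration = 20, hrv_sd_bpm = 2, seed = 3)
  pulse <- make_pulse_train(tt, ecg$r_peak_times, delay = 0.214)
  drift <- 0.8 * sin(2 * pi * 0.13 * tt) + 0.3 * tt / max(tt)
  dims <- c(8, 8, 6)
  set.seed(4)
  map_pulse <- array(exp(-((row(matrix(0, 8, 8)) - 4)^2 +
                             (col(matrix(0, 8, 8)) - 4)^2) / 6), c(8, 8, 1))
  map_pulse <- array(rep(map_pulse, 6), dims)
  map_drift <- array(1, dims)
  vel <- outer(as.numeric(map_pulse), pulse) +
    outer(as.numeric(map_drift), drift) +
    matrix(rnorm(prod(dims) * length(tt), 0, 0.02), prod(dims))
  ks <- structure(list(velocity = array(vel, c(dims, length(tt))),
                       framerate_hz = fr), class = "rca_kasai")
  tr <- extract_pulse_component(ks, seed = 1)
  expect_gt(abs(stats::cor(tr$values, pulse)), 0.95)
  tr2 <- extract_pulse_component(ks, seed = 1)
  expect_identical(tr$values, tr2$values) # seeded determinism

  # peak detection then heart-rate agreement with the driving ECG
  pk <- detect_pulse_peaks(tr, min_interval_s = 0.4, k_mad = 3)
  expect_equal(length(pk), length(ecg$r_peak_times))
  hr_us <- heart_rate(pk)
  hr_ecg <- heart_rate(ecg$r_peak_times)
  expect_lt(abs(mean(hr_us) - mean(hr_ecg)), 0.5)
  ba <- bland_altman(hr_us, hr_ecg)
  expect_lt(ba$loa_high - ba$bias, ecg$hrv_sd_bpm) # tighter than the HRV
  # transit time recovered within one slow-time frame
  pt <- pwtt(ecg$r_peak_times, pk)
  expect_lt(abs(pt$mean - 0.214), 1 / fr)

  flat <- ks
  flat$velocity <- array(rnorm(length(flat$velocity), 0, 1e-3),
                         dim(flat$velocity))
  expect_error(extract_pulse_component(flat, seed = 1), "no pulse")
})

test_that("peak detection honours spacing and thresholds", {
  fr <- 200
  tt <- seq(0, 10 - 1 / fr, by = 1 / fr)
  v <- make_pulse_train(tt, seq(0.5, 9.5, by = 1))
  pk <- detect_pulse_peaks(v, min_interval_s = 0.4, framerate_hz = fr)
  expect_equal(diff(pk), rep(1, length(pk) - 1), tolerance = 1e-9)
  expect_length(detect_pulse_peaks(rep(1, 2000), framerate_hz = fr), 0)
})

test_that("heart rate and Bland-Altman behave per definition", {
  expect_equal(heart_rate(c(0, 1, 2)), c(60, 60))
  expect_equal(heart_rate(c(0, 0.8608)), 69.7, tolerance = 0.01)
  expect_error(heart_rate(1), "at least 2")

  a <- c(60, 62, 61, 63)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  bad <- bland_altman(a + 2, a)
  expect_equal(bad$bias, 2)
  expect_equal(bad$loa_high - bad$loa_low, 0)
  set.seed(9)
  x <- rnorm(500, 70, 3)
  ba <- bland_altman(x + rnorm(500, 0, 0.87), x)
  expect_equal(ba$loa_high - ba$bias, 1.96 * 0.87, tolerance = 0.1)
  expect_error(bland_altman(1:3, 1:4), "length mismatch")
})

test_that("PWTT pairs beats to preceding R-peaks and PWV divides distance by delay", {
  pt <- pwtt(c(0, 1), c(0.214, 1.214))
  expect_equal(pt$delays, c(0.214, 0.214))
  expect_equal(pwv(0.88, pt$mean), 4.112, tolerance = 1e-3)
  expect_equal(pwtt(c(0, 1, 2), c(0, 1, 2))$delays, c(0, 0, 0))
  drop1 <- pwtt(c(0, 1, 2), c(0.2, 2.2))
  expect_equal(drop1$n, 2)
  expect_equal(drop1$dropped, 0)
  expect_error(pwtt(c(0, 1), c(5, 6)), "no pairable")
  expect_equal(pwv(1, 1), 1)
  expect_equal(pwv(2 * 0.88, 0.214), 2 * pwv(0.88, 0.214))
  expect_error(pwv(-1, 0.2), "positive")
})

test_that("peak widths at half prominence match closed forms", {
  fr <- 1000
  tt <- seq(0, 2 - 1 / fr, by = 1 / fr)
  g <- exp(-(tt - 1)^2 / (2 * 0.0276^2))
  w <- peak_fwhm(g, peaks = 1, framerate_hz = fr)
  expect_equal(w, 2.355 * 0.0276, tolerance = 0.01) # ~65 ms
  expect_equal(peak_fwhm(5 * g, peaks = 1, framerate_hz = fr), w,
               tolerance = 1e-6)
  tri <- pmax(0, 1 - abs(tt - 1) / 0.2) # base 0.4 s
  expect_equal(peak_fwhm(tri, peaks = 1, framerate_hz = fr), 0.2,
               tolerance = 0.01)
})
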