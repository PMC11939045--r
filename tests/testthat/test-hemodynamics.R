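test_that("PBV series measures percent change from baseline", {
  pd <- matrix(5, 10, 40)
  expect_true(all(pbv_series(pd, baseline_window = 1:10)$pbv_pct == 0))
  pd2 <- cbind(matrix(5, 10, 20), matrix(10, 10, 20))
  pv <- pbv_series(pd2, baseline_window = 1:20)
  expect_equal(pv$pbv_pct[40], 100)
  gen <- make_stimulus_pbv(noise_sd = 0, seed = 1)
  pv2 <- pbv_series(matrix(gen$truth, 1), baseline_window = 1:15)
  expect_equal(pv2$pbv_pct[length(gen$time)], 113, tolerance = 1)
  expect_error(pbv_series(matrix(0, 4, 10), baseline_window = 1:3),
               "zero baseline")
})

test_that("the tri-level stimulus regressor codes the protocol", {
  r <- stimulus_regressor(stimulus_protocol())
  expect_length(r, 60)
  expect_equal(sum(r == 0), 15)
  expect_equal(sum(r == -1), 15)
  expect_equal(sum(r == 1), 30)
  expect_equal(sum(abs(r)), 45) # stimulated frames
  quiet <- stimulus_protocol(baseline_s = 30, cold_s = 0, hot_s = 0)
  expect_true(all(stimulus_regressor(quiet) == 0))
  rh <- stimulus_regressor(stimulus_protocol(), coding = "hot_only")
  expect_true(all(rh %in% c(0, 1)))
  expect_equal(sum(rh), 30)
})

test_that("Fisher z maps match the closed form and flag activation", {
  n <- 103
  set.seed(2)
  reg <- rep(c(-1, 0, 1), length.out = n)
  # construct a series with sample correlation exactly 0.5
  y <- 0.5 * scale(reg)[, 1] +
    sqrt(0.75) * scale(resid(lm(rnorm(n) ~ reg)))[, 1]
  z <- zscore_map(matrix(y, 1), reg)
  expect_equal(as.numeric(z), atanh(0.5) * sqrt(n - 3), tolerance = 1e-6)
  expect_equal(atanh(0.5) * sqrt(100), 5.4931, tolerance = 1e-4)

  expect_equal(as.numeric(zscore_map(matrix(rep(1, n), 1), reg)), 0)

  # a voxel tracking the regressor tops the map
  set.seed(3)
  vox <- matrix(rnorm(50 * n), 50)
  vox[7, ] <- reg + rnorm(n, 0, 0.1)
  zm <- zscore_map(vox, reg)
  expect_equal(which.max(abs(zm)), 7L)
})

test_that("Bonferroni thresholds equal inverse-normal quantiles", {
  # independent oracle: invert the normal CDF numerically
  inv <- function(p) stats::uniroot(function(q) stats::pnorm(q) - p,
                                    c(0, 10), tol = 1e-10)$root
  expect_equal(bonferroni_threshold(0.05, 1, 1), inv(0.95),
               tolerance = 1e-6)
  thr <- bonferroni_threshold(0.001, 9.6 * 9.6 * 5, 0.0158)
  n_tests <- 9.6 * 9.6 * 5 / 0.0158 # ~2.9e4 voxel-resolution cells
  expect_equal(thr, inv(1 - 0.001 / n_tests), tolerance = 1e-6)
  expect_equal(thr, 5.4, tolerance = 0.05) # the in vivo significance level
  expect_gt(bonferroni_threshold(0.001, 100, 0.01),
            bonferroni_threshold(0.001, 10, 0.01))
  expect_warning(t0 <- bonferroni_threshold(0.5, 1, 10), "degenerates")
  expect_equal(t0, 0)
})

test_that("gamma-difference responses integrate kernels against the stimulus", {
  t <- seq(0, 100, by = 0.5)
  stim <- as.numeric(t >= 10)
  f0 <- hrf_fit(a1 = 9, b1 = 1.59, amplitude = 2, baseline = 1)
  expect_equal(f0$rise_time_s, 8 * 1.59, tolerance = 0.01)
  resp <- gamma_diff_response(t, f0, stim)
  expect_equal(resp[length(resp)], 1 + 2, tolerance = 0.01) # plateau
  expect_true(all(diff(resp) > -1e-9)) # monotone when w = 0
  none <- gamma_diff_response(t, hrf_fit(amplitude = 0, baseline = 3), stim)
  expect_true(all(abs(none - 3) < 1e-12))
  expect_error(gamma_diff_response(c(0, 1, 3), f0, c(0, 1, 1)), "uniform")
})

test_that("HRF fitting recovers generator parameters", {
  gen <- make_stimulus_pbv(noise_sd = 0, seed = 1)
  fit <- fit_hrf(gen$truth, stimulus_protocol(), seed = 1)
  expect_equal(fit$rise_time_s, 14.3, tolerance = 0.01)
  expect_equal(fit$duration_sd_s, 8.4, tolerance = 0.01)
  expect_equal(fit$amplitude, 1.13, tolerance = 0.01)

  flat <- rep(1, length(gen$time))
  ff <- fit_hrf(flat, stimulus_protocol(), seed = 1)
  expect_lt(abs(ff$amplitude), 0.02)

  gl <- glance(fit)
  expect_true(all(c("rise_time_s", "duration_sd_s", "rss") %in% names(gl)))
  td <- tidy(fit)
  expect_equal(nrow(td), 7)
})

test_that("family-wise error of thresholded noise maps stays controlled", {
  n_maps <- 200; n_vox <- 500; n_t <- 60
  reg <- stimulus_regressor(stimulus_protocol())
  thr <- bonferroni_threshold(0.001, n_vox, 1) # one test per voxel
  exceed <- 0; hits <- 0
  for (k in seq_len(n_maps)) {
    set.seed(3000 + k)
    m <- matrix(rnorm(n_vox * n_t), n_vox)
    z <- zscore_map(m, reg)
    exceed <- exceed + sum(abs(z) > thr)
    hits <- hits + any(abs(z) > thr)
  }
  expect_lte(exceed / (n_maps * n_vox), 0.001) # voxel-wise exceedances
  expect_lte(hits, 3) # ~0.4 expected family-wise hits in 200 maps
})

test_that("group comparisons defer to the standard tests", {
  set.seed(5)
  x <- rnorm(10)
  same <- group_stats(x, x, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  y <- x + rnorm(10, 0, 1e-6)
  near <- group_stats(x, y, paired = TRUE)
  expect_gt(near$p_value, 0.05)
  a <- rnorm(10); b <- rnorm(10, 5, 1)
  w <- group_stats(a, b)
  expect_lt(w$p_value, 0.001)
  expect_equal(w$test, "Welch")
  set.seed(6)
  u <- runif(500)
  expect_lt(stats::shapiro.test(u)$p.value, 0.05)
  expect_error(group_stats(1:5, 1:4, paired = TRUE), "equal lengths")
})
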