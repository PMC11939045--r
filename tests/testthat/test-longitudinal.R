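test_that("vesselness highlights tubes over blobs and vanishes on constants", {
  tube <- synth_tube_volume()
  resp <- vesselness(tube, scales = c(1.5e-4, 3e-4))
  ctr <- resp$values[, 20, 12]
  bgm <- stats::median(resp$values)
  expect_gt(stats::median(ctr), 5 * max(bgm, 1e-6))

  blob <- tube
  blob$values <- blob$values * 0
  d <- dim(blob$values)
  for (ix in seq_len(d[1])) {
    blob$values[ix, , ] <- exp(-((ix - 20)^2) / 8) *
      tube$values[20, , ]
  }
  vb <- vesselness(blob, scales = c(1.5e-4, 3e-4))
  # compare raw (pre-normalisation) responses at matched contrast via the
  # tube response evaluated on each input
  expect_gt(max(resp$values[, 20, 12]),
            max(vb$values[18:22, 20, 12]) * 0.99)
  expect_gt(mean(resp$values[, 20, 12] > 0.5),
            mean(vb$values[, 20, 12] > 0.5))

  flat <- tube
  flat$values <- array(3, dim(flat$values))
  vf <- vesselness(flat, scales = 2e-4)
  expect_true(all(vf$values == 0))
})

test_that("vessel segmentation thresholds monotonically and drops specks", {
  tube <- synth_tube_volume()
  resp <- vesselness(tube, scales = c(1.5e-4, 3e-4))
  seg <- segment_vessels(resp, 0.3)
  # tube core forms one connected component spanning the x axis
  lab <- rcaflow:::.label_components_cpp(seg, dim(seg))
  main <- which.max(tabulate(lab))
  xs <- which(apply(lab == main, 1, any))
  expect_equal(length(xs), dim(seg)[1])
  hi <- segment_vessels(resp, 0.6)
  expect_true(all(!hi | seg)) # higher threshold is a subset
  expect_error(segment_vessels(resp, 1), "empty")

  # isolated small specks are removed
  sp <- resp
  sp$values[2, 2, 2] <- 1
  seg2 <- segment_vessels(sp, 0.3)
  expect_false(seg2[2, 2, 2])
})

test_that("rigid transforms compose, invert and resample consistently", {
  tf <- rigid_transform(c(3, -2, 5), c(4e-4, -2e-4, 3e-4))
  inv <- invert_rigid(tf)
  idc <- compose_rigid(inv, tf)
  expect_equal(idc$rotation_deg, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(idc$translation_m, c(0, 0, 0), tolerance = 1e-12)

  tube <- synth_tube_volume(noise_sd = 0.02, seed = 2)
  ctr <- grid_center(tube$grid)
  tf2 <- rigid_transform(c(0, 0, 4), c(3e-4, -2e-4, 0), center = ctr)
  moved <- apply_rigid(tube, tf2)
  back <- apply_rigid(moved, invert_rigid(tf2))
  ins <- attr(back, "inside") & attr(moved, "inside")
  core <- ins
  core[c(1:4, 37:40), , ] <- FALSE
  expect_gt(stats::cor(back$values[core], tube$values[core]), 0.98)
})

test_that("registration recovers imposed transforms to 0.1 mm and 0.5 degrees", {
  tube <- synth_tube_volume(dims = c(36, 36, 20), noise_sd = 0, seed = 3)
  # break the x-translation degeneracy of a straight tube with a second
  # oblique branch
  d <- dim(tube$values)
  for (ix in seq_len(d[1])) {
    iy <- round(10 + 0.4 * ix)
    if (iy >= 2 && iy <= d[2] - 1) {
      tube$values[ix, (iy - 1):(iy + 1), 8:10] <-
        tube$values[ix, (iy - 1):(iy + 1), 8:10] + 0.8
    }
  }
  set.seed(11)
  tube$values <- tube$values + rnorm(length(tube$values), 0, 0.05)
  ctr <- grid_center(tube$grid)
  cases <- list(c(0, 0, 5, 8e-4, -3e-4, 2e-4),
                c(0, 0, -3, -5e-4, 5e-4, 0))
  for (cs in cases) {
    tf_true <- rigid_transform(cs[1:3], cs[4:6], center = ctr)
    moving <- apply_rigid(tube, tf_true)
    res <- register_rigid(moving, tube)
    rec <- invert_rigid(res$transform) # aligning moving back equals inverse
    expect_true(res$converged)
    expect_lt(max(abs(rec$rotation_deg - tf_true$rotation_deg)), 0.5)
    expect_lt(max(abs(rec$translation_m - tf_true$translation_m)), 1e-4)
  }

  same <- register_rigid(tube, tube)
  expect_lt(max(abs(same$transform$rotation_deg)), 0.2)
  expect_lt(max(abs(same$transform$translation_m)), 5e-5)

  set.seed(12)
  g <- tube$grid
  n1 <- rcaflow:::new_volume(array(rnorm(prod(d)), d), g)
  n2 <- rcaflow:::new_volume(array(rnorm(prod(d)), d), g)
  res2 <- register_rigid(n1, n2)
  expect_true(!res2$converged || res2$ncc < 0.2)
})

test_that("volume correlations rise after registration and separate fingers", {
  base <- synth_tube_volume(dims = c(30, 30, 16), seed = 6)
  ctr <- grid_center(base$grid)
  tf <- rigid_transform(c(0, 0, 4), c(5e-4, -3e-4, 0), center = ctr)
  set.seed(21)
  scan1 <- base$values + rnorm(length(base$values), 0, 0.05)
  mv <- apply_rigid(rcaflow:::new_volume(scan1, base$grid), tf)
  scan2 <- mv$values + rnorm(length(scan1), 0, 0.05)
  v2 <- rcaflow:::new_volume(scan2, base$grid)
  r_unreg <- pearson_corr_volumes(v2, base)
  reg <- register_rigid(v2, base)
  aligned <- apply_rigid(v2, reg$transform)
  r_reg <- pearson_corr_volumes(aligned, base,
                                mask = attr(aligned, "inside"))
  expect_gt(r_reg, r_unreg)

  # same-phantom repeats correlate above different-phantom pairs
  same <- numeric(10); diffr <- numeric(10)
  for (k in 1:10) {
    set.seed(100 + k)
    a <- base$values + rnorm(length(base$values), 0, 0.2)
    b <- base$values + rnorm(length(base$values), 0, 0.2)
    other <- synth_tube_volume(dims = c(30, 30, 16), axis = "y",
                               seed = 200 + k)
    same[k] <- stats::cor(a, b)
    diffr[k] <- stats::cor(a, other$values +
                             rnorm(length(base$values), 0, 0.2))
  }
  gs <- group_stats(same, diffr)
  expect_lt(gs$p_value, 0.001)
  expect_error(pearson_corr_volumes(base, rcaflow:::new_volume(
    array(1, dim(base$values)), base$grid)), "zero-variance")
})

test_that("common-volume fractions follow box geometry", {
  fov <- list(x = c(-4.8e-3, 4.8e-3), y = c(-4.8e-3, 4.8e-3),
              z = c(0, 9.6e-3))
  expect_equal(common_volume_fraction(rigid_transform(), fov), 1)
  tfx <- rigid_transform(translation_m = c(0.83e-3, 0, 0))
  expect_equal(common_volume_fraction(tfx, fov), (9.6 - 0.83) / 9.6,
               tolerance = 0.01)
  tfr <- rigid_transform(c(0, 0, 5.3), c(0.83e-3, 0, 0),
                         center = c(0, 0, 4.8e-3))
  f1 <- common_volume_fraction(tfr, fov)
  f2 <- common_volume_fraction(invert_rigid(tfr), fov)
  expect_equal(f1, f2, tolerance = 0.01)
  expect_gt(f1, 0.84) # the in vivo worst case keeps 84% of the FOV
})
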