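# Shared fixtures for the test suite. Everything is generated in code at
# test time; seeds are fixed for reproducibility.

small_array <- function(n = 16L) array_spec(n, n, 150e-6)

fast_pulse <- function() pulse_spec(fs = 50e6)

# synthetic IQ volume series with prescribed per-voxel amplitude and a
# slow-time phase/velocity model: phase advances by 4*pi*f0*vz/(c*fr) per
# frame in voxels selected by `moving_mask`
synth_iq_series <- function(dims = c(6, 6, 6), n_slow = 80,
                            framerate_hz = 500, f0 = 9.02e6, c = 1480,
                            vz = 0, moving_mask = NULL, noise_sd = 0,
                            seed = 1L) {
  set.seed(seed)
  nvox <- prod(dims)
  if (is.null(moving_mask)) moving_mask <- array(TRUE, dims)
  amp <- complex(real = rnorm(nvox), imaginary = rnorm(nvox))
  dphi <- 4 * pi * f0 * vz / (c * framerate_hz)
  ph <- outer(ifelse(as.logical(moving_mask), dphi, 0), 0:(n_slow - 1))
  dat <- array(amp * exp(1i * ph), c(dims, n_slow))
  if (noise_sd > 0) {
    dat <- dat + array(complex(real = rnorm(nvox * n_slow, 0, noise_sd),
                               imaginary = rnorm(nvox * n_slow, 0, noise_sd)),
                       c(dims, n_slow))
  }
  g <- voxel_grid(seq_len(dims[1]) * 1e-4, seq_len(dims[2]) * 1e-4,
                  seq_len(dims[3]) * 1e-4)
  iq_volume_series(dat, g, framerate_hz, f0)
}

# small flow-tube fixture shared by the Doppler acceptance studies
cnr_tube <- function(seed = 3L) {
  make_flow_tube(diameter = 500e-6, depth = 3e-3, axis = c(1, 0, 0),
                 speed = 0.01, length = 3e-3, blood_density = 10,
                 gel_density = 5, seed = seed,
                 box = list(x = c(-1.5e-3, 1.5e-3), y = c(-1.2e-3, 1.2e-3),
                            z = c(2.2e-3, 4.4e-3)))
}

cnr_grid <- function() {
  voxel_grid(seq(-1.2e-3, 1.2e-3, by = 1.2e-4),
             seq(-1.1e-3, 1.1e-3, by = 1.1e-4),
             seq(2.3e-3, 4.4e-3, by = 8e-5))
}

# background shell at depth offset from the tube (axial PSF falls off far
# faster than lateral, so this region is noise-dominated)
cnr_background <- function(grid) {
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  zarr <- array(rep(grid$z, each = dims[1] * dims[2]), dims)
  zarr > 3.9e-3
}

# gaussian-profile synthetic tube volume for vesselness/registration tests
synth_tube_volume <- function(dims = c(40, 40, 24), radius_vox = 2,
                              axis = "x", value = 1, noise_sd = 0,
                              seed = 1L) {
  set.seed(seed)
  g <- voxel_grid(seq_len(dims[1]) * 1e-4, seq_len(dims[2]) * 1e-4,
                  seq_len(dims[3]) * 1e-4)
  cy <- dims[2] / 2; cz <- dims[3] / 2
  v <- array(0, dims)
  for (iy in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    v[, iy, iz] <- value * exp(-((iy - cy)^2 + (iz - cz)^2) /
                                 (2 * radius_vox^2))
  }
  if (axis == "y") v <- aperm(v, c(2, 1, 3))
  if (noise_sd > 0) v <- v + array(rnorm(prod(dims), 0, noise_sd), dims)
  new_vol <- structure(list(values = v, grid = g), class = "rca_volume")
  new_vol
}
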