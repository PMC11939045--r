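#' Digital phantoms
#'
#' Phantoms are collections of point scatterers with compartment labels
#' (`bead`, `gel`, `blood`, `tissue`) and, for flow phantoms, a kinematic
#' description: each moving scatterer lives on a vessel segment and is
#' advected along its axis, re-entering at the inlet when it leaves the far
#' end so the scatterer density stays stationary. All generators are pure
#' functions of their parameters and seed.
#'
#' @name phantoms
NULL

new_phantom <- function(positions, amplitude, labels, medium, seed,
                        flow = NULL, waveform = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            length(amplitude) == nrow(positions),
            length(labels) == nrow(positions))
  if (nrow(positions) > 0 && any(positions[, 3] < 0)) {
    stop("scatterer depth z must be >= 0", call. = FALSE)
  }
  structure(
    list(positions = positions, amplitude = amplitude, labels = labels,
         medium = medium, seed = seed, flow = flow, waveform = waveform),
    class = "rca_phantom"
  )
}

#' @export
print.rca_phantom <- function(x, ...) {
  cat(sprintf("<rca_phantom> %d scatterers (%s)\n", nrow(x$positions),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Point-target (bead) phantom
#'
#' A single static point scatterer on the array axis, the digital analogue
#' of a sub-resolution metal bead used for PSF measurements.
#'
#' @param depth Depth of the target in metres.
#' @param amplitude Reflectivity.
#' @param medium An [medium_spec()].
#' @return An `rca_phantom`.
#' @export
make_bead_phantom <- function(depth = 4.8e-3, amplitude = 1,
                              medium = medium_spec()) {
  stopifnot(depth > 0)
  new_phantom(matrix(c(0, 0, depth), 1, 3), amplitude, "bead", medium,
              seed = 0L)
}

# default field of view for scatterer placement, from the array aperture
default_fov <- function(array = array_spec(), depth = c(0.5e-3, 8e-3)) {
  h <- aperture(array) / 2
  list(x = c(-h, h), y = c(-h, h), z = depth)
}

#' Flow-tube phantom
#'
#' A cylindrical vessel of given diameter and depth filled with moving blood
#' scatterers at `speed` along `axis`, embedded in static gel speckle.
#' Scatterer counts are Poisson draws from the given densities; blood
#' scatterers recycle at the tube inlet.
#'
#' @param diameter Tube diameter in metres.
#' @param depth Tube centreline depth in metres.
#' @param axis Flow direction (unit vector, defaults to +x).
#' @param speed Mean flow speed in m/s.
#' @param length Tube length in metres (centred on the origin).
#' @param blood_density,gel_density Scatterers per cubic millimetre.
#' @param box Gel region as a list with `x`, `y`, `z` ranges in metres;
#'   defaults to a block around the tube.
#' @param fov Field of view used to validate the tube position.
#' @param seed Integer seed.
#' @param medium An [medium_spec()].
#' @return An `rca_phantom`.
#' @export
make_flow_tube <- function(diameter = 500e-6, depth = 3e-3,
                           axis = c(1, 0, 0), speed = 0.01,
                           length = 4e-3,
                           blood_density = 10, gel_density = 5,
                           box = NULL, fov = default_fov(),
                           seed = 1L, medium = medium_spec()) {
  stopifnot(diameter > 0, blood_density >= 0, gel_density >= 0, length > 0)
  axis <- axis / sqrt(sum(axis^2))
  r <- diameter / 2
  if (depth - r < min(fov$z) || depth + r > max(fov$z) ||
      length / 2 > max(fov$x)) {
    stop("flow tube lies outside the field of view", call. = FALSE)
  }
  if (is.null(box)) {
    box <- list(x = c(-length / 2, length / 2), y = c(-1.5e-3, 1.5e-3),
                z = depth + c(-1e-3, 1e-3))
    box$z[1] <- max(box$z[1], 0.2e-3)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # orthonormal frame of the tube
  p0 <- c(0, 0, depth) - axis * length / 2
  e1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])

  vol_mm3 <- pi * (r * 1e3)^2 * (length * 1e3)
  n_b <- stats::rpois(1, blood_density * vol_mm3)
  s0 <- stats::runif(n_b, 0, length)
  rho <- r * sqrt(stats::runif(n_b))
  th <- stats::runif(n_b, 0, 2 * pi)
  perp <- outer(rho * cos(th), e1) + outer(rho * sin(th), e2)
  pos_b <- matrix(rep(p0, each = n_b), n_b, 3) + outer(s0, axis) + perp

  bvol_mm3 <- prod(vapply(box, diff, 0)) * 1e9
  n_g <- stats::rpois(1, gel_density * bvol_mm3)
  pos_g <- cbind(stats::runif(n_g, box$x[1], box$x[2]),
                 stats::runif(n_g, box$y[1], box$y[2]),
                 stats::runif(n_g, box$z[1], box$z[2]))
  # drop gel scatterers inside the lumen
  rel <- pos_g - matrix(rep(p0, each = n_g), n_g, 3)
  ax_c <- rel %*% axis
  rad2 <- rowSums((rel - outer(as.numeric(ax_c), axis))^2)
  keep <- rad2 > r^2 | ax_c < 0 | ax_c > length
  pos_g <- pos_g[keep, , drop = FALSE]

  n <- n_b + nrow(pos_g)
  flow <- NULL
  if (n_b > 0) {
    flow <- list(
      vessels = list(list(p0 = p0, axis = axis, length = length,
                          radius = r, v_mean = speed)),
      scat_vessel = c(rep(1L, n_b), rep(0L, nrow(pos_g))),
      s0 = c(s0, rep(0, nrow(pos_g))),
      perp = rbind(perp, matrix(0, nrow(pos_g), 3))
    )
  }
  wf <- list(type = "constant")
  new_phantom(rbind(pos_b, pos_g),
              c(stats::rnorm(n_b, 1, 0.2), stats::rnorm(nrow(pos_g), 1, 0.2)),
              c(rep("blood", n_b), rep("gel", nrow(pos_g))),
              medium, seed, flow = flow, waveform = wf)
}

#' Pulsatile flow waveform
#'
#' Dimensionless periodic speed modulation w(t): a raised-cosine systolic
#' upstroke peaking at `t_peak` followed by an exponential diastolic decay
#' towards the end-diastolic level. The waveform is scaled so its time mean
#' is 1 (multiplying the mean speed) and its resistive index
#' `(max - min)/max` equals `ri`.
#'
#' @param hr_bpm Heart rate, beats per minute.
#' @param ri Target resistive index in `[0, 1)`.
#' @param t_peak_frac,tau_frac Systolic peak time and diastolic decay
#'   constant, as fractions of the cardiac period.
#' @return A list with the waveform function `w(t)`, its cumulative integral
#'   `W(t)` and the period.
#' @export
pulse_waveform_fn <- function(hr_bpm = 70, ri = 0.57,
                              t_peak_frac = 0.15, tau_frac = 0.12) {
  stopifnot(hr_bpm > 0, ri >= 0, ri < 1)
  period <- 60 / hr_bpm
  tp <- t_peak_frac * period
  tau <- tau_frac * period
  shape <- function(tau_c) { # tau_c in [0, period)
    ifelse(tau_c <= tp,
           0.5 * (1 - cos(pi * tau_c / tp)),
           exp(-(tau_c - tp) / tau))
  }
  # dense grid over one period for normalization and integration
  tt <- seq(0, period, length.out = 2049)
  sh <- shape(tt %% period)
  sh[length(sh)] <- sh[1]
  w_min_frac <- min(sh) # ~0; end-diastolic level before RI shaping
  # w_raw = (1 - ri) + ri * shape  has max 1, min ~ (1 - ri): RI = ri
  raw <- (1 - ri) + ri * sh
  m <- mean(raw[-length(raw)])
  wfun <- function(t) ((1 - ri) + ri * shape(t %% period)) / m
  Wtab <- cumsum(c(0, (raw[-1] + raw[-length(raw)]) / 2 * diff(tt))) / m
  Wfun <- function(t) {
    k <- floor(t / period)
    r <- t - k * period
    k * Wtab[length(Wtab)] + stats::approx(tt, Wtab, r, rule = 2)$y
  }
  list(type = "pulsatile", w = wfun, W = Wfun, period = period,
       hr_bpm = hr_bpm, ri = ri, w_min = min(raw) / m, w_max = max(raw) / m,
       w_min_frac = w_min_frac)
}

#' Branching vascular-tree phantom
#'
#' A subcutaneous plexus of small vessels (300-800 um diameter around 1 mm
#' deep) fed by one deeper, larger artery (~1 mm diameter at ~4 mm), with
#' pulsatile flow shared across segments and static tissue speckle around
#' them. Segments may also be supplied explicitly via `spec$segments`, each
#' a list with `p0`, `p1`, `diameter` and `v_mean`, which turns the
#' generator into a deterministic fixture builder (e.g. two parallel tubes
#' at a 334-um centre gap for resolvability tests).
#'
#' @param spec A list of tree parameters; see Details. Fields:
#'   `n_plexus`, `plexus_depth`, `plexus_diam`, `artery_depth`,
#'   `artery_diam`, `v_plexus`, `v_artery`, `hr_bpm`, `ri`,
#'   `blood_density`, `tissue_density`, `extent`, `segments`, `pulsatile`.
#' @param seed Integer seed.
#' @param medium An [medium_spec()].
#' @return An `rca_phantom`.
#' @export
make_vascular_tree <- function(spec = list(), seed = 1L,
                               medium = medium_spec()) {
  p <- utils::modifyList(list(
    n_plexus = 5L, plexus_depth = 1e-3, plexus_diam = c(300e-6, 800e-6),
    artery_depth = 4e-3, artery_diam = 1e-3,
    v_plexus = 5e-3, v_artery = 0.02, hr_bpm = 70, ri = 0.57,
    blood_density = 10, tissue_density = 5, extent = 4e-3,
    segments = NULL, pulsatile = TRUE), spec)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h <- p$extent / 2

  segs <- p$segments
  if (is.null(segs)) {
    segs <- list(list(p0 = c(-h, 0, p$artery_depth),
                      p1 = c(h, 0, p$artery_depth),
                      diameter = p$artery_diam, v_mean = p$v_artery))
    for (i in seq_len(p$n_plexus)) {
      ang <- stats::runif(1, 0, pi)
      y0 <- stats::runif(1, -h * 0.8, h * 0.8)
      d <- stats::runif(1, p$plexus_diam[1], p$plexus_diam[2])
      z <- p$plexus_depth + stats::runif(1, -0.2e-3, 0.2e-3)
      dirv <- c(cos(ang), sin(ang), 0)
      mid <- c(stats::runif(1, -h / 2, h / 2), y0, z)
      segs <- c(segs, list(list(p0 = mid - dirv * h, p1 = mid + dirv * h,
                                diameter = d, v_mean = p$v_plexus)))
    }
    # one vertical feeder from the artery up to the plexus
    xf <- 0
    segs <- c(segs, list(list(p0 = c(xf, 0, p$artery_depth),
                              p1 = c(xf, 0, p$plexus_depth),
                              diameter = 0.4e-3, v_mean = p$v_plexus)))
  }
  depth_ok <- vapply(segs, function(s) {
    min(s$p0[3], s$p1[3]) - s$diameter / 2 >= 0
  }, TRUE)
  if (!all(depth_ok)) stop("vessel radii/depths outside the field of view",
                           call. = FALSE)

  pos <- NULL; s0 <- NULL; perp <- NULL; vid <- NULL
  vessels <- list()
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    axisv <- s$p1 - s$p0
    len <- sqrt(sum(axisv^2)); axisv <- axisv / len
    r <- s$diameter / 2
    e1 <- if (abs(axisv[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * axisv) * axisv; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axisv[2] * e1[3] - axisv[3] * e1[2],
            axisv[3] * e1[1] - axisv[1] * e1[3],
            axisv[1] * e1[2] - axisv[2] * e1[1])
    vol_mm3 <- pi * (r * 1e3)^2 * (len * 1e3)
    nb <- stats::rpois(1, p$blood_density * vol_mm3)
    if (nb == 0) nb <- 1L
    ss <- stats::runif(nb, 0, len)
    rho <- r * sqrt(stats::runif(nb)); th <- stats::runif(nb, 0, 2 * pi)
    pp <- outer(rho * cos(th), e1) + outer(rho * sin(th), e2)
    pos <- rbind(pos, matrix(s$p0, nb, 3, byrow = TRUE) +
                   outer(ss, axisv) + pp)
    s0 <- c(s0, ss); perp <- rbind(perp, pp); vid <- c(vid, rep(i, nb))
    vessels[[i]] <- list(p0 = s$p0, axis = axisv, length = len, radius = r,
                         v_mean = s$v_mean)
  }
  n_b <- nrow(pos)
  # static tissue speckle in the block
  vol_mm3 <- (p$extent * 1e3)^2 * ((p$artery_depth + 1e-3) * 1e3)
  nt_ <- stats::rpois(1, p$tissue_density * vol_mm3)
  pos_t <- cbind(stats::runif(nt_, -h, h), stats::runif(nt_, -h, h),
                 stats::runif(nt_, 0.2e-3, p$artery_depth + 1e-3))
  wf <- if (p$pulsatile) pulse_waveform_fn(p$hr_bpm, p$ri) else
    list(type = "constant")
  flow <- list(vessels = vessels,
               scat_vessel = c(vid, rep(0L, nt_)),
               s0 = c(s0, rep(0, nt_)),
               perp = rbind(perp, matrix(0, nt_, 3)))
  new_phantom(rbind(pos, pos_t),
              c(stats::rnorm(n_b, 1, 0.2), stats::rnorm(nt_, 1, 0.2)),
              c(rep("blood", n_b), rep("tissue", nt_)),
              medium, seed, flow = flow, waveform = wf)
}

#' Advance a phantom to a slow time
#'
#' Moves each flowing scatterer along its vessel axis by the integral of its
#' speed; scatterers passing the far end re-enter at the inlet (modular
#' advection), keeping the per-vessel count and density stationary. Static
#' scatterers are unchanged. Also records the instantaneous velocity of each
#' scatterer at `t` in the `velocity` field.
#'
#' @param phantom An `rca_phantom`.
#' @param t Slow time in seconds (>= 0).
#' @return The advanced `rca_phantom`.
#' @export
advance_phantom <- function(phantom, t) {
  stopifnot(t >= 0)
  if (is.null(phantom$flow) || t == 0) {
    if (is.null(phantom$velocity)) {
      phantom$velocity <- instantaneous_velocity(phantom, t)
    }
    return(phantom)
  }
  fl <- phantom$flow
  W <- if (phantom$waveform$type == "pulsatile") phantom$waveform$W(t) else t
  pos <- phantom$positions
  for (i in seq_along(fl$vessels)) {
    v <- fl$vessels[[i]]
    sel <- fl$scat_vessel == i
    if (!any(sel)) next
    s <- (fl$s0[sel] + v$v_mean * W) %% v$length
    pos[sel, ] <- matrix(v$p0, sum(sel), 3, byrow = TRUE) +
      outer(s, v$axis) + fl$perp[sel, , drop = FALSE]
  }
  phantom$positions <- pos
  phantom$velocity <- instantaneous_velocity(phantom, t)
  phantom
}

instantaneous_velocity <- function(phantom, t) {
  v <- matrix(0, nrow(phantom$positions), 3)
  if (is.null(phantom$flow)) return(v)
  w <- if (phantom$waveform$type == "pulsatile") phantom$waveform$w(t) else 1
  fl <- phantom$flow
  for (i in seq_along(fl$vessels)) {
    ves <- fl$vessels[[i]]
    sel <- fl$scat_vessel == i
    if (any(sel)) v[sel, ] <- matrix(ves$axis * ves$v_mean * w,
                                     sum(sel), 3, byrow = TRUE)
  }
  v
}

#' Binary flow mask of a phantom on a voxel grid
#'
#' Marks voxels whose centre lies inside any vessel lumen; the ground truth
#' for CNR and detection metrics.
#'
#' @param phantom An `rca_phantom` with flow.
#' @param grid A [voxel_grid()].
#' @return Logical array `[nx, ny, nz]`.
#' @export
flow_mask <- function(phantom, grid) {
  m <- array(FALSE, c(length(grid$x), length(grid$y), length(grid$z)))
  if (is.null(phantom$flow)) return(m)
  gx <- grid$x; gy <- grid$y; gz <- grid$z
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- rep(FALSE, nrow(pts))
  for (v in phantom$flow$vessels) {
    rel <- pts - matrix(v$p0, nrow(pts), 3, byrow = TRUE)
    ax <- as.numeric(rel %*% v$axis)
    rad2 <- rowSums((rel - outer(ax, v$axis))^2)
    inside <- inside | (rad2 <= v$radius^2 & ax >= 0 & ax <= v$length)
  }
  array(inside, dim(m))
}

#' Synthetic ECG R-peak train
#'
#' R-peak times with beat-to-beat variability: successive intervals are
#' `60 / N(hr_bpm, hrv_sd_bpm)` truncated positive.
#'
#' @param hr_bpm Mean heart rate.
#' @param duration Total duration in seconds.
#' @param hrv_sd_bpm Standard deviation of the per-beat rate.
#' @param seed Integer seed.
#' @return An object of class `rca_ecg` with `r_peak_times`, `hr_bpm`,
#'   `hrv_sd_bpm`.
#' @export
make_ecg_trace <- function(hr_bpm = 70, duration = 60, hrv_sd_bpm = 2,
                           seed = 1L) {
  stopifnot(hr_bpm > 0, duration > 0, hrv_sd_bpm >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  peaks <- 0
  t <- 0
  repeat {
    bpm <- stats::rnorm(1, hr_bpm, hrv_sd_bpm)
    while (bpm <= 1) bpm <- stats::rnorm(1, hr_bpm, hrv_sd_bpm)
    t <- t + 60 / bpm
    if (t > duration) break
    peaks <- c(peaks, t)
  }
  structure(list(r_peak_times = peaks, hr_bpm = hr_bpm,
                 hrv_sd_bpm = hrv_sd_bpm, duration = duration),
            class = "rca_ecg")
}

#' Thermal-stimulus protocol
#'
#' Baseline / cold / hot immersion protocol sampled at the power-Doppler
#' volume rate: by default 30 s baseline, 30 s cold (5 C), 60 s hot (42 C)
#' at 0.5 volumes per second.
#'
#' @param baseline_s,cold_s,hot_s Segment durations in seconds.
#' @param doppler_rate_hz Power-Doppler volume rate in Hz.
#' @return An object of class `rca_protocol`.
#' @export
stimulus_protocol <- function(baseline_s = 30, cold_s = 30, hot_s = 60,
                              doppler_rate_hz = 0.5) {
  stopifnot(baseline_s > 0, cold_s >= 0, hot_s >= 0, doppler_rate_hz > 0)
  structure(list(baseline_s = baseline_s, cold_s = cold_s, hot_s = hot_s,
                 doppler_rate_hz = doppler_rate_hz),
            class = "rca_protocol")
}

#' Synthetic peripheral-blood-volume response
#'
#' Generates PBV time courses under the thermal protocol: unity baseline, a
#' transient dip after the cold stimulus (a gamma-shaped transient - the
#' cold response has no canonical fitted form, so this is a modelling
#' choice), and a sustained rise after the hot stimulus following the
#' cumulative gamma kernel whose mode and SD are `rise_time_s` and
#' `duration_sd_s`. Defaults reproduce a +113% plateau with a 14.3 s rise
#' and 8.4 s duration.
#'
#' @param protocol A [stimulus_protocol()].
#' @param rise_time_s Kernel mode (stimulus-to-peak time of the response
#'   rate), seconds.
#' @param duration_sd_s Kernel standard deviation, seconds.
#' @param hot_gain Fractional plateau increase over baseline (1.13 = +113%).
#' @param cold_dip Peak fractional dip after the cold stimulus.
#' @param noise_sd Gaussian noise SD as a fraction of baseline.
#' @param n_voxels Number of independent noisy traces.
#' @param seed Integer seed.
#' @return A list with `time`, `pbv` (`n_voxels` x time matrix), the
#'   noiseless `truth`, and the generating parameters.
#' @export
make_stimulus_pbv <- function(protocol = stimulus_protocol(),
                              rise_time_s = 14.3, duration_sd_s = 8.4,
                              hot_gain = 1.13, cold_dip = 0.27,
                              noise_sd = 0.05, n_voxels = 1, seed = 1L) {
  dt <- 1 / protocol$doppler_rate_hz
  total <- protocol$baseline_s + protocol$cold_s + protocol$hot_s
  time <- seq(0, total - dt, by = dt)
  g <- gamma_from_mode_sd(rise_time_s, duration_sd_s)
  t_hot <- protocol$baseline_s + protocol$cold_s
  t_cold <- protocol$baseline_s
  hot <- stats::pgamma(pmax(time - t_hot, 0), shape = g$shape,
                       scale = g$scale)
  cold_kernel <- function(tau) {
    k <- stats::dgamma(pmax(tau, 0), shape = 2, scale = 3)
    k / stats::dgamma(3, shape = 2, scale = 3) # unit peak
  }
  cold <- cold_kernel(time - t_cold)
  truth <- 1 + hot_gain * hot - cold_dip * cold
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pbv <- matrix(rep(truth, each = n_voxels), n_voxels, length(time)) +
    matrix(stats::rnorm(n_voxels * length(time), 0, noise_sd),
           n_voxels, length(time))
  list(time = time, pbv = pbv, truth = truth,
       params = list(rise_time_s = rise_time_s, duration_sd_s = duration_sd_s,
                     hot_gain = hot_gain, cold_dip = cold_dip,
                     shape = g$shape, scale = g$scale, t_hot = t_hot,
                     t_cold = t_cold))
}

# shape/scale of a gamma kernel from its mode and SD
gamma_from_mode_sd <- function(mode, sd) {
  stopifnot(mode > 0, sd > 0)
  rho <- mode / sd
  s <- (rho + sqrt(rho^2 + 4)) / 2 # sqrt(shape)
  list(shape = s^2, scale = sd / s)
}
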