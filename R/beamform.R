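#' Voxel grid
#'
#' Strictly increasing voxel-centre coordinates (metres); z runs from the
#' array plane into the medium.
#'
#' @param x,y,z Coordinate vectors in metres.
#' @return An object of class `rca_grid`.
#' @export
voxel_grid <- function(x, y, z) {
  stopifnot(all(diff(x) > 0) || length(x) == 1,
            all(diff(y) > 0) || length(y) == 1,
            all(diff(z) > 0) || length(z) == 1, all(z >= 0))
  structure(list(x = x, y = y, z = z), class = "rca_grid")
}

#' Default beamforming grid
#'
#' Half-wavelength lateral and quarter-wavelength axial spacing around a
#' region of interest.
#'
#' @param pulse,medium Acoustic specs defining the wavelength.
#' @param xlim,ylim,zlim Extents in metres.
#' @param lateral_frac,axial_frac Spacing as fractions of the wavelength.
#' @return An `rca_grid`.
#' @export
default_grid <- function(pulse = pulse_spec(), medium = medium_spec(),
                         xlim = c(-2e-3, 2e-3), ylim = c(-2e-3, 2e-3),
                         zlim = c(3.8e-3, 5.8e-3),
                         lateral_frac = 0.5, axial_frac = 0.25) {
  lam <- wavelength(pulse, medium)
  voxel_grid(seq(xlim[1], xlim[2], by = lam * lateral_frac),
             seq(ylim[1], ylim[2], by = lam * lateral_frac),
             seq(zlim[1], zlim[2], by = lam * axial_frac))
}

#' @export
print.rca_grid <- function(x, ...) {
  cat(sprintf("<rca_grid> %d x %d x %d voxels\n",
              length(x$x), length(x$y), length(x$z)))
  invisible(x)
}

#' IQ demodulation of RF channel data
#'
#' Mixes the real RF down by `f0` and low-pass filters (zero-phase spectral
#' filter with a raised-cosine transition band), optionally decimating. The
#' complex baseband preserves the envelope of in-band echoes.
#'
#' @param data An `rca_channel_data` with `domain == "rf"`.
#' @param f0 Demodulation frequency in Hz.
#' @param decim Integer decimation factor applied after filtering.
#' @param bw Low-pass cutoff in Hz (defaults to `0.75 * f0`).
#' @return Baseband `rca_channel_data`.
#' @export
demodulate <- function(data, f0 = NULL, decim = 1L, bw = NULL) {
  stopifnot(inherits(data, "rca_channel_data"))
  if (data$domain != "rf") {
    stop("data are already baseband: double demodulation", call. = FALSE)
  }
  f0 <- f0 %||% data$pulse$f0
  bw <- bw %||% (0.75 * f0)
  d <- dim(data$samples)
  nt <- d[1]
  t <- data$t0 + (seq_len(nt) - 1) / data$fs
  mixer <- exp(-2i * pi * f0 * t)
  x <- matrix(as.complex(data$samples), nt) * mixer
  # zero-phase spectral low-pass with Hann roll-off
  fr <- (seq_len(nt) - 1) / nt * data$fs
  fr <- ifelse(fr > data$fs / 2, fr - data$fs, fr)
  roll <- 0.25 * bw
  H <- ifelse(abs(fr) <= bw, 1,
              ifelse(abs(fr) <= bw + roll,
                     0.5 * (1 + cos(pi * (abs(fr) - bw) / roll)), 0))
  X <- stats::mvfft(x)
  x <- stats::mvfft(X * H, inverse = TRUE) / nt
  if (decim > 1) {
    keep <- seq(1, nt, by = decim)
    x <- x[keep, , drop = FALSE]
    nt <- length(keep)
  }
  out <- data
  out$samples <- array(x, c(nt, d[2], d[3], d[4]))
  out$fs <- data$fs / decim
  out$domain <- "baseband"
  out$f0 <- f0
  out
}

new_iq_series <- function(data, grid, framerate_hz, f0, provenance = "") {
  structure(list(data = data, grid = grid, framerate_hz = framerate_hz,
                 f0 = f0, provenance = provenance, filtered = FALSE),
            class = "rca_iq_series")
}

#' Construct an IQ volume series
#'
#' Container for beamformed complex volumes over slow time, dimensioned
#' `[nx, ny, nz, n_slow]`.
#'
#' @param data Complex 4D array.
#' @param grid A [voxel_grid()].
#' @param framerate_hz Slow-time sampling rate.
#' @param f0 Carrier frequency used for the baseband phase.
#' @param provenance Free-text origin tag (e.g. scheme name).
#' @return An `rca_iq_series`.
#' @export
iq_volume_series <- function(data, grid, framerate_hz, f0 = 9.02e6,
                             provenance = "") {
  stopifnot(length(dim(data)) == 4, inherits(grid, "rca_grid"),
            dim(data)[1] == length(grid$x), dim(data)[2] == length(grid$y),
            dim(data)[3] == length(grid$z))
  new_iq_series(data, grid, framerate_hz, f0, provenance)
}

#' @export
print.rca_iq_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rca_iq_series> %dx%dx%d voxels, %d frames at %.4g Hz (%s)\n",
              d[1], d[2], d[3], d[4], x$framerate_hz, x$provenance))
  invisible(x)
}

das_events <- function(data, grid, medium, events_idx, rx_fnumber,
                       apodization, tx_apodization = "hann") {
  sch <- data$scheme
  n_ev <- length(events_idx)
  tx_axis <- integer(n_ev); tx_kind <- integer(n_ev)
  ang <- numeric(n_ev); tau0 <- numeric(n_ev); src <- numeric(n_ev)
  wts <- rep(1, n_ev)
  pos <- element_positions(sch$array, "rows")
  half_len <- (sch$array$n_rows - 1) / 2 * sch$array$pitch
  n_el <- sch$array$n_rows
  for (q in seq_len(n_ev)) {
    ev <- sch$events[[events_idx[q]]]
    tx_axis[q] <- if (ev$tx_axis == "rows") 0L else 1L
    if (sch$name %in% c("SPW", "OPW")) {
      tx_kind[q] <- 0L
      ang[q] <- ev$steer_angle_deg * pi / 180
      tau0[q] <- half_len * abs(sin(ang[q])) / medium$c
    } else {
      tx_kind[q] <- 1L
      act <- which(ev$polarities != 0)
      if (length(act) != 1) {
        stop("delay-and-sum needs single-element events; decode HSA data ",
             "first", call. = FALSE)
      }
      src[q] <- pos[act]
      if (tx_apodization == "hann") {
        # synthetic-transmit-aperture apodization across the element grid
        wts[q] <- 0.5 - 0.5 * cos(2 * pi * (act - 1) / (n_el - 1))
      }
    }
  }
  sub <- data$samples[, , events_idx, , drop = FALSE]
  # the envelope peaks half a pulse after the wavefront: sample at
  # tau + t_center by shifting the time origin
  t0_eff <- data$t0 - (data$t_center %||% 0)
  .das_series_cpp(sub, dim(sub), grid$x, grid$y, grid$z,
                  tx_axis, tx_kind, ang, tau0, src, wts, pos,
                  medium$c, data$f0, data$fs, t0_eff,
                  rx_fnumber, if (apodization == "hann") 1L else 0L)
}

#' Delay-and-sum of a single transmit event
#'
#' 3D RCA delay-and-sum: the transmit delay is evaluated in the steering
#' plane (ideal plane wave, or cylindrical wave from the active element for
#' synthetic aperture) and the receive delay in the orthogonal plane, with a
#' Hann dynamic receive aperture of width `z / rx_fnumber`. Baseband samples
#' are phase-rotated by `exp(+2i pi f0 tau)`.
#'
#' @param data Baseband `rca_channel_data`.
#' @param event_index Which event to beamform.
#' @param grid A [voxel_grid()].
#' @param medium An [medium_spec()].
#' @param rx_fnumber Receive f-number (0 or negative = full aperture).
#' @param apodization `"hann"` or `"rect"`.
#' @return Complex array `[nx, ny, nz]`.
#' @export
das_rca <- function(data, event_index, grid, medium = medium_spec(),
                    rx_fnumber = 1, apodization = c("hann", "rect")) {
  apodization <- match.arg(apodization)
  stopifnot(inherits(data, "rca_channel_data"))
  if (data$domain != "baseband") stop("demodulate RF data first",
                                      call. = FALSE)
  res <- das_events(data, grid, medium, event_index, rx_fnumber, apodization,
                    tx_apodization = "none")
  v <- if (res$w_rows_ev > 0) res$rows_tx else res$cols_tx
  array(v, c(length(grid$x), length(grid$y), length(grid$z)))
}

#' Beamform a full ensemble into an IQ volume series
#'
#' Per slow-time frame, every event is delay-and-summed and the volumes are
#' coherently averaged. For orthogonal plane waves the rows-transmit and
#' columns-transmit halves are each averaged and then combined coherently
#' (`combine = "coherent"`), or returned separately
#' (`combine = "split"`, the input XDoppler needs). HSA data must be
#' Hadamard-decoded first.
#'
#' @param data Baseband `rca_channel_data`.
#' @param grid A [voxel_grid()].
#' @param medium An [medium_spec()].
#' @param rx_fnumber Receive f-number (default 1).
#' @param apodization Receive apodization window.
#' @param tx_apodization Apodization across synthetic-aperture transmit
#'   events (`"hann"` or `"none"`); the event grid of an SA/HSA acquisition
#'   is a spatial transmit aperture, and windowing it sets the transmit-axis
#'   side-lobe floor. Ignored for plane-wave schemes, whose angle
#'   compounding stays unweighted.
#' @param combine `"coherent"` or `"split"`.
#' @return An `rca_iq_series`, or a list of two for `combine = "split"`.
#' @export
beamform_series <- function(data, grid, medium = medium_spec(),
                            rx_fnumber = 1,
                            apodization = c("hann", "rect"),
                            tx_apodization = c("hann", "none"),
                            combine = c("coherent", "split")) {
  apodization <- match.arg(apodization)
  tx_apodization <- match.arg(tx_apodization)
  combine <- match.arg(combine)
  stopifnot(inherits(data, "rca_channel_data"))
  if (data$domain != "baseband") stop("demodulate RF data first",
                                      call. = FALSE)
  sch <- data$scheme
  if (sch$name == "HSA" && !isTRUE(data$decoded)) {
    stop("HSA channel data must be hadamard_decode()d before beamforming",
         call. = FALSE)
  }
  d <- dim(data$samples)
  res <- das_events(data, grid, medium, seq_len(d[3]), rx_fnumber,
                    apodization, tx_apodization)
  fr <- data$prf_hz / sch$n_events
  dims <- c(length(grid$x), length(grid$y), length(grid$z), d[4])
  if (combine == "split") {
    if (res$w_rows_ev == 0 || res$w_cols_ev == 0) {
      stop("split compounding needs both transmit orientations (OPW)",
           call. = FALSE)
    }
    a <- new_iq_series(array(res$rows_tx / res$w_rows_ev, dims), grid, fr,
                       data$f0, paste0(sch$name, ":rows_tx"))
    b <- new_iq_series(array(res$cols_tx / res$w_cols_ev, dims), grid, fr,
                       data$f0, paste0(sch$name, ":cols_tx"))
    return(list(rows_tx = a, cols_tx = b))
  }
  tot <- (res$rows_tx + res$cols_tx) / (res$w_rows_ev + res$w_cols_ev)
  new_iq_series(array(tot, dims), grid, fr, data$f0, sch$name)
}

#' Simulate and beamform a long ensemble in slow-time blocks
#'
#' Convenience wrapper around [simulate_ensemble()], [add_noise()],
#' [hadamard_decode()] and [beamform_series()] that processes the slow-time
#' dimension in blocks so channel data never have to be held in memory for
#' the whole acquisition. Noise is drawn per block with a block-derived
#' seed.
#'
#' @param phantom An `rca_phantom`.
#' @param scheme An `rca_scheme`.
#' @param grid A [voxel_grid()].
#' @param pulse,medium Acoustic specs.
#' @param n_frames Total compound frames.
#' @param block Frames per block.
#' @param snr_db Channel SNR passed to [add_noise()] (`Inf` = noiseless).
#' @param seed Base seed for the noise.
#' @param depth_max Recordable depth, metres.
#' @param tx_model Transmit model for [simulate_ensemble()].
#' @param fs_baseband Baseband sampling rate.
#' @param rx_fnumber,apodization Beamforming options.
#' @param combine `"coherent"` or `"split"` (see [beamform_series()]).
#' @return An `rca_iq_series` (or a list of two for `combine = "split"`).
#' @export
acquire_iq_series <- function(phantom, scheme, grid, pulse = pulse_spec(),
                              medium = medium_spec(), n_frames = 100,
                              block = 100, snr_db = Inf, seed = 1L,
                              depth_max = 4e-3,
                              tx_model = c("element", "plane"),
                              fs_baseband = 20e6,
                              rx_fnumber = 1, apodization = "hann",
                              combine = c("coherent", "split")) {
  tx_model <- match.arg(tx_model)
  combine <- match.arg(combine)
  frame_dt <- scheme$n_events / scheme$prf_hz
  starts <- seq(1, n_frames, by = block)
  out <- NULL
  for (bi in seq_along(starts)) {
    nb <- min(block, n_frames - starts[bi] + 1)
    cd <- simulate_ensemble(phantom, scheme, pulse, medium, n_frames = nb,
                            depth_max = depth_max, domain = "baseband",
                            fs_baseband = fs_baseband, tx_model = tx_model,
                            t0_slow = (starts[bi] - 1) * frame_dt)
    if (is.finite(snr_db)) cd <- add_noise(cd, snr_db, seed = seed + bi)
    if (scheme$name == "HSA") cd <- hadamard_decode(cd)
    iq <- beamform_series(cd, grid, medium, rx_fnumber = rx_fnumber,
                          apodization = apodization, combine = combine)
    if (is.null(out)) {
      out <- iq
    } else if (combine == "coherent") {
      out$data <- abind4(out$data, iq$data)
    } else {
      out$rows_tx$data <- abind4(out$rows_tx$data, iq$rows_tx$data)
      out$cols_tx$data <- abind4(out$cols_tx$data, iq$cols_tx$data)
    }
  }
  out
}

# bind two 4D arrays along slow time
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0i, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' XDoppler power from the two OPW orientations
#'
#' Doppler power formed by correlating, instead of coherently summing, the
#' rows-transmit and columns-transmit beamformed series:
#' `|sum_t V_rt(t) * Conj(V_ct(t))| / n_slow` per voxel. Noise terms that
#' are independent between the two orientations average out.
#'
#' @param series_rt,series_ct Clutter-filtered `rca_iq_series`, one per
#'   orientation, on the same grid and frame rate.
#' @return Power volume (`rca_volume`).
#' @export
xdoppler_power <- function(series_rt, series_ct) {
  stopifnot(inherits(series_rt, "rca_iq_series"),
            inherits(series_ct, "rca_iq_series"))
  if (!identical(dim(series_rt$data), dim(series_ct$data))) {
    stop("orientation series have mismatched dimensions", call. = FALSE)
  }
  n <- dim(series_rt$data)[4]
  v <- Mod(apply(series_rt$data * Conj(series_ct$data), c(1, 2, 3), sum)) / n
  new_volume(v, series_rt$grid)
}

new_volume <- function(values, grid) {
  structure(list(values = values, grid = grid), class = "rca_volume")
}

#' @export
print.rca_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rca_volume> %d x %d x %d\n", d[1], d[2], d[3]))
  invisible(x)
}

#' B-mode (log-compressed envelope) volume
#'
#' `20 * log10(|v| / max|v|)`: 0 dB at the brightest voxel.
#'
#' @param volume Complex array or `rca_iq_series` frame.
#' @param grid Optional [voxel_grid()] when `volume` is a bare array.
#' @param frame Frame index when given an `rca_iq_series`.
#' @return `rca_volume` in dB.
#' @export
bmode <- function(volume, grid = NULL, frame = 1L) {
  if (inherits(volume, "rca_iq_series")) {
    grid <- volume$grid
    volume <- volume$data[, , , frame]
  }
  m <- max(Mod(volume))
  if (m == 0) stop("all-zero volume has no B-mode", call. = FALSE)
  new_volume(20 * log10(pmax(Mod(volume), m * 1e-10) / m), grid)
}
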