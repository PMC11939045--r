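#' Sampled excitation waveform
#'
#' Hann-windowed sinusoid of duration `n_cycles / f0` sampled at `fs`. The
#' window makes the burst zero-mean and keeps its spectral peak within 2% of
#' `f0`.
#'
#' @param spec An [pulse_spec()].
#' @return Numeric vector of samples starting at t = 0, with attributes
#'   `fs` and `t` (sample times).
#' @export
pulse_waveform <- function(spec) {
  stopifnot(inherits(spec, "rca_pulse"))
  dur <- spec$n_cycles / spec$f0
  t <- seq(0, dur, by = 1 / spec$fs)
  w <- 0.5 * (1 - cos(2 * pi * t / dur)) * sin(2 * pi * spec$f0 * t)
  attr(w, "fs") <- spec$fs
  attr(w, "t") <- t
  w
}

# Hann envelope of the pulse (for direct baseband synthesis)
pulse_envelope <- function(spec) {
  dur <- spec$n_cycles / spec$f0
  t <- seq(0, dur, by = 1 / spec$fs)
  e <- 0.5 * (1 - cos(2 * pi * t / dur))
  attr(e, "fs") <- spec$fs
  e
}

#' Transducer two-way impulse response
#'
#' Linear-phase sinusoid at `f0` with a Gaussian envelope whose spectrum
#' has the pulse's fractional -6 dB (amplitude) bandwidth; the received
#' echo is the excitation convolved with this response.
#'
#' @param spec An [pulse_spec()] with non-NULL `bandwidth_frac`.
#' @return Sampled impulse response with attributes `fs` and `center`
#'   (peak-envelope sample index).
#' @export
transducer_ir <- function(spec) {
  stopifnot(!is.null(spec$bandwidth_frac))
  sigma_f <- spec$bandwidth_frac * spec$f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(3 * sigma_t * spec$fs)
  t <- (-half:half) / spec$fs
  ir <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * spec$f0 * t)
  attr(ir, "fs") <- spec$fs
  attr(ir, "center") <- half + 1L
  ir
}

# effective transmitted/received pulse tables used by the simulator:
# RF pulse (excitation (x) transducer IR) and its Hilbert envelope,
# plus the envelope-peak time for beamforming group-delay correction.
effective_pulse_tables <- function(spec) {
  exc <- as.numeric(pulse_waveform(spec))
  if (is.null(spec$bandwidth_frac)) {
    env <- Mod(analytic_signal(exc))
    t_center <- (which.max(env) - 1) / spec$fs
    return(list(rf = exc, env = env, fs = spec$fs, t_center = t_center))
  }
  ir <- transducer_ir(spec)
  rf <- stats::convolve(exc, rev(as.numeric(ir)), type = "open")
  # shift so the table still starts at t = 0 physically: the IR is
  # linear-phase with its centre at (center-1)/fs, so the convolution
  # starts (center-1) samples early
  rf <- rf / max(abs(rf))
  env <- Mod(analytic_signal(rf))
  t_center <- (which.max(env) - 1) / spec$fs - (attr(ir, "center") - 1) / spec$fs
  list(rf = rf, env = env, fs = spec$fs, t_center = t_center,
       t_start = -(attr(ir, "center") - 1) / spec$fs)
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Strip-element directivity
#'
#' Far-field directivity of a strip element in its steering plane:
#' `|sinc(width * sin(angle) / wavelength)| * cos(angle)`, normalized to 1 at
#' broadside. This is what attenuates high-angle plane waves on a
#' wavelength-pitch array.
#'
#' @param angle Angle from the element normal, radians.
#' @param width Element width in metres.
#' @param wavelength Wavelength in metres.
#' @return Gain in `[0, 1]`.
#' @export
element_directivity <- function(angle, width, wavelength) {
  stopifnot(all(abs(angle) < pi / 2))
  x <- width * sin(angle) / wavelength
  s <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  abs(s) * cos(angle)
}

new_channel_data <- function(samples, fs, prf_hz, scheme, domain, t0,
                             f0 = NULL, medium = NULL, pulse = NULL,
                             t_center = 0) {
  structure(
    list(samples = samples, fs = fs, prf_hz = prf_hz, scheme = scheme,
         domain = domain, t0 = t0, f0 = f0, medium = medium, pulse = pulse,
         t_center = t_center, decoded = FALSE),
    class = "rca_channel_data"
  )
}

#' @export
print.rca_channel_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "<rca_channel_data> %s, %d samples x %d rx x %d events x %d frames, fs %.3g MHz\n",
    x$domain, d[1], d[2], d[3], d[4], x$fs / 1e6))
  invisible(x)
}

# Per-event descriptors handed to the C++ kernel
event_descriptors <- function(scheme, medium, tx_model) {
  n_el <- scheme$array$n_rows
  pos <- element_positions(scheme$array, "rows") # same grid for both axes
  n_ev <- scheme$n_events
  tx_axis <- integer(n_ev)
  tx_mode <- integer(n_ev)
  pol <- matrix(0, n_el, n_ev)
  fire <- matrix(0, n_el, n_ev)
  ang <- numeric(n_ev)
  tau0 <- numeric(n_ev)
  half_len <- (n_el - 1) / 2 * scheme$array$pitch
  for (e in seq_len(n_ev)) {
    ev <- scheme$events[[e]]
    tx_axis[e] <- if (ev$tx_axis == "rows") 0L else 1L
    plane_kind <- scheme$name %in% c("SPW", "OPW")
    if (plane_kind && tx_model == "plane") {
      tx_mode[e] <- 1L
      ang[e] <- ev$steer_angle_deg * pi / 180
      tau0[e] <- half_len * abs(sin(ang[e])) / medium$c
    } else {
      tx_mode[e] <- 0L
      pol[, e] <- ev$polarities
      if (plane_kind) {
        fire[, e] <- plane_wave_delays(ev$steer_angle_deg, pos, medium$c)
      }
      ang[e] <- ev$steer_angle_deg * pi / 180
      tau0[e] <- half_len * abs(sin(ang[e])) / medium$c
    }
  }
  list(tx_axis = tx_axis, tx_mode = tx_mode, pol = pol, fire = fire,
       angle = ang, tau0 = tau0, elem_pos = pos)
}

#' Simulate an ensemble of RF (or baseband) channel data
#'
#' Linear time-of-flight scattering model: every scatterer re-emits a delayed
#' copy of the excitation, with delays given by the strip-element RCA
#' geometry (transmit distance in the steering plane, receive distance in the
#' orthogonal plane) and amplitudes weighted by the strip directivity.
#' Scatterers are frozen within a compound frame and advanced between frames
#' by [advance_phantom()], so the slow-time Doppler phase of moving blood
#' emerges from the geometry rather than being imposed.
#'
#' Two transmit models are available. The default `"element"` model
#' superposes a delayed cylindrical wavelet from every active element, which
#' reproduces the finite-aperture edge waves that set plane-wave side-lobe
#' levels. The `"plane"` model replaces a steered transmission by an ideal
#' infinite plane wave; it is considerably faster and adequate for Doppler
#' ensemble studies where only the echo dynamics matter. HSA ensembles are
#' synthesised by simulating the single-element events and Hadamard-encoding
#' them, which is algebraically identical to firing all elements with +-1
#' polarities in this linear model.
#'
#' @param phantom An `rca_phantom`.
#' @param scheme An `rca_scheme`.
#' @param pulse An [pulse_spec()].
#' @param medium An [medium_spec()].
#' @param n_frames Number of compound frames (slow-time samples).
#' @param depth_max Maximum recordable depth in metres (sets the time
#'   window).
#' @param domain `"rf"` for real radio-frequency sampling at `pulse$fs`, or
#'   `"baseband"` for directly synthesised complex IQ at `fs_baseband`.
#' @param fs_baseband Output sampling rate when `domain = "baseband"`.
#' @param tx_model `"element"` or `"plane"` (see Details).
#' @param directivity Apply the strip-element directivity model.
#' @param hsa_fast Synthesise HSA by encoding simulated single-element
#'   events (exact in the linear model) instead of superposing all active
#'   elements per event; disable to exercise the direct path.
#' @param t0_slow Slow-time origin of the first frame in seconds (lets long
#'   ensembles be simulated in blocks).
#' @return An `rca_channel_data`, samples dimensioned
#'   `[time, rx_channel, event, frame]`.
#' @export
simulate_ensemble <- function(phantom, scheme, pulse = pulse_spec(),
                              medium = medium_spec(), n_frames = 1,
                              depth_max = 8e-3,
                              domain = c("rf", "baseband"),
                              fs_baseband = 20e6,
                              tx_model = c("element", "plane"),
                              directivity = TRUE, hsa_fast = TRUE,
                              t0_slow = 0) {
  domain <- match.arg(domain)
  tx_model <- match.arg(tx_model)
  stopifnot(inherits(phantom, "rca_phantom"), inherits(scheme, "rca_scheme"))
  if (nrow(phantom$positions) > 0 &&
      max(phantom$positions[, 3]) > depth_max) {
    stop("phantom extends beyond depth_max: scatterers outside the ",
         "recordable window", call. = FALSE)
  }
  hsa_fast <- scheme$name == "HSA" && isTRUE(hsa_fast)
  sim_scheme <- scheme
  if (hsa_fast) {
    sim_scheme <- build_scheme("SA", scheme$array, prf_hz = scheme$prf_hz)
  }
  desc <- event_descriptors(sim_scheme, medium, tx_model)

  tabs <- effective_pulse_tables(pulse)
  t_start <- tabs$t_start %||% 0

  # recordable window: two-way depth_max plus firing delays and the pulse
  zr <- if (nrow(phantom$positions)) range(phantom$positions[, 3]) else c(0, depth_max)
  dur <- length(tabs$rf) / pulse$fs
  t_min <- max(0, 2 * zr[1] / medium$c + t_start - 2e-7)
  t_max <- 2 * depth_max / medium$c + max(desc$tau0, desc$fire) + dur + 2e-7
  fs_out <- if (domain == "rf") pulse$fs else fs_baseband
  nt <- ceiling((t_max - t_min) * fs_out) + 1L

  tab <- if (domain == "rf") tabs$rf else tabs$env
  dom_code <- if (domain == "rf") 0L else 1L

  frame_dt <- scheme$n_events / scheme$prf_hz
  n_rx <- scheme$array$n_rows
  n_ev <- sim_scheme$n_events
  out <- array(if (domain == "rf") 0 else 0 + 0i,
               dim = c(nt, n_rx, n_ev, n_frames))
  for (fi in seq_len(n_frames)) {
    ph <- advance_phantom(phantom, t0_slow + (fi - 1) * frame_dt)
    fr <- .sim_frame_cpp(ph$positions, ph$amplitude,
                         desc$tx_axis, desc$tx_mode, desc$pol, desc$fire,
                         desc$angle, desc$tau0, desc$elem_pos,
                         as.numeric(tab), pulse$fs, dom_code, pulse$f0,
                         fs_out, t_min - t_start, nt, medium$c,
                         scheme$array$element_width, directivity)
    out[, , , fi] <- fr
  }
  cd <- new_channel_data(out, fs_out, scheme$prf_hz,
                         if (hsa_fast) sim_scheme else scheme,
                         domain, t_min,
                         f0 = if (domain == "baseband") pulse$f0 else NULL,
                         medium = medium, pulse = pulse,
                         t_center = tabs$t_center)
  if (hsa_fast) {
    cd <- hadamard_encode(cd)
    cd$scheme <- scheme
  }
  cd
}

#' Add channel noise at a prescribed SNR
#'
#' Adds iid Gaussian noise scaled so that
#' `10 * log10(signal power / noise power) = snr_db`, with the signal power
#' measured over nonzero-signal samples. Complex data get independent noise
#' in both quadratures with the same total power.
#'
#' @param data An `rca_channel_data`.
#' @param snr_db Target SNR in dB; `Inf` returns the input unchanged.
#' @param seed Integer seed (noise is reproducible).
#' @return Noisy `rca_channel_data`.
#' @export
add_noise <- function(data, snr_db, seed = 1L) {
  stopifnot(inherits(data, "rca_channel_data"))
  if (is.infinite(snr_db)) return(data)
  s <- data$samples
  nz <- Mod(s) > 0
  if (!any(nz)) {
    stop("all-zero channel data: SNR-relative noise scaling is undefined",
         call. = FALSE)
  }
  p_sig <- mean(Mod(s[nz])^2)
  p_noise <- p_sig * 10^(-snr_db / 10)
  n <- length(s)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.complex(s)) {
    noise <- complex(real = stats::rnorm(n, sd = sqrt(p_noise / 2)),
                     imaginary = stats::rnorm(n, sd = sqrt(p_noise / 2)))
  } else {
    noise <- stats::rnorm(n, sd = sqrt(p_noise))
  }
  data$samples <- s + noise
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
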