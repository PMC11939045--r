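#' Kasai phase-shift velocity estimation
#'
#' Axial tissue velocity from the phase of the lag-1 slow-time
#' autocorrelation of the unfiltered IQ series (tissue signal retained):
#' `v(t) = c * framerate * arg(s_t * Conj(s_{t-1})) / (4 pi f0)`, positive
#' towards the array. The lag-1 products are averaged over a small
#' spatio-temporal kernel before taking the argument (variance reduction).
#' Displacements above an eighth of a wavelength per frame wrap.
#'
#' @param series An `rca_iq_series` before clutter filtering.
#' @param f0 Carrier frequency (defaults to the series').
#' @param c Speed of sound, m/s.
#' @param kernel Averaging kernel half-widths `c(x, y, z, t)` in samples
#'   (full width `2k+1`, except slow time: `k+1`).
#' @return An `rca_kasai` with the velocity array `[nx, ny, nz, n_slow-1]`
#'   and `framerate_hz`.
#' @export
kasai_phase_shift <- function(series, f0 = NULL, c = 1480,
                              kernel = c(1, 1, 1, 1)) {
  stopifnot(inherits(series, "rca_iq_series"))
  if (isTRUE(series$filtered)) {
    warning("Kasai estimation on clutter-filtered data: tissue motion has ",
            "been removed", call. = FALSE)
  }
  f0 <- f0 %||% series$f0
  d <- dim(series$data)
  if (d[4] < 2) stop("need at least two slow-time frames", call. = FALSE)
  lag <- series$data[, , , -1, drop = FALSE] *
    Conj(series$data[, , , -d[4], drop = FALSE])
  lag <- box_smooth_4d(lag, kernel)
  v <- c * series$framerate_hz * Arg(lag) / (4 * pi * f0)
  structure(list(velocity = v, framerate_hz = series$framerate_hz,
                 grid = series$grid, f0 = f0, c = c),
            class = "rca_kasai")
}

# separable moving-average over the 4 dimensions (half-widths h >= 0)
box_smooth_4d <- function(a, h) {
  d <- dim(a)
  for (ax in 1:4) {
    if (h[ax] <= 0 || d[ax] == 1) next
    a <- apply_axis_ma(a, ax, h[ax])
  }
  a
}

apply_axis_ma <- function(a, ax, h) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:4, ax))
  m <- aperm(a, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  n <- dm[1]
  out <- m * 0
  cnt <- numeric(n)
  for (off in -h:h) {
    src <- pmin(pmax(seq_len(n) + off, 1), n) # edge replication
    out <- out + m[src, , drop = FALSE]
  }
  out <- out / (2 * h + 1)
  dim(out) <- dm
  aperm(out, order(perm))
}

#' Extract the cardiac pulse component from Kasai volumes
#'
#' SVD of the Casorati form of the Kasai velocity series keeps the first
#' `n_modes` temporal vectors (the dominant motions of the tissue); a
#' seeded symmetric ICA (tanh contrast) unmixes them into independent
#' motion sources, and the component with the largest fraction of spectral
#' power in the cardiac band (0.7-3 Hz plus its first harmonic) is
#' returned, with its sign fixed so the dominant deflection is positive.
#'
#' @param kasai An `rca_kasai`.
#' @param n_modes Number of SVD temporal modes retained (default 5).
#' @param n_ica Number of ICA components (default `n_modes`).
#' @param seed Integer seed for the ICA initialisation.
#' @param band Cardiac band in Hz.
#' @param min_fraction Minimum cardiac-band fraction below which no pulse is
#'   declared.
#' @return An `rca_pulse_trace` with `values`, `framerate_hz`, `time`, and
#'   diagnostics (`band_fractions`, `mixing`).
#' @export
extract_pulse_component <- function(kasai, n_modes = 5L, n_ica = n_modes,
                                    seed = 1L, band = c(0.7, 3),
                                    min_fraction = 0.3) {
  stopifnot(inherits(kasai, "rca_kasai"))
  d <- dim(kasai$velocity)
  nt <- d[4]
  if (nt < 20 * n_modes) {
    stop("ensemble too short: need at least ", 20 * n_modes,
         " slow-time samples for ", n_modes, " modes", call. = FALSE)
  }
  C <- matrix(kasai$velocity, prod(d[1:3]), nt)
  G <- crossprod(C)
  eg <- eigen(G, symmetric = TRUE)
  sv <- sqrt(pmax(eg$values, 0))
  # energy-weighted temporal modes
  Tm <- t(eg$vectors[, seq_len(n_modes), drop = FALSE]) * sv[seq_len(n_modes)]
  ica <- fast_ica_symm(Tm, n_comp = n_ica, seed = seed)
  fr <- kasai$framerate_hz
  fracs <- apply(ica$S, 1, function(s) cardiac_band_fraction(s, fr, band))
  if (max(fracs) < min_fraction) {
    stop("no pulse detected: best cardiac-band fraction ",
         signif(max(fracs), 3), " < ", min_fraction, call. = FALSE)
  }
  best <- which.max(fracs)
  tr <- ica$S[best, ]
  if (abs(min(tr)) > abs(max(tr))) tr <- -tr
  structure(list(values = tr, framerate_hz = fr,
                 time = (seq_along(tr) - 1) / fr,
                 band_fractions = fracs, mixing = ica$W,
                 component = best, singular_values = sv),
            class = "rca_pulse_trace")
}

cardiac_band_fraction <- function(s, fr, band = c(0.7, 3)) {
  n <- length(s)
  p <- Mod(stats::fft(s - mean(s)))[1:floor(n / 2)]^2
  f <- (seq_len(floor(n / 2)) - 1) * fr / n
  inb <- (f >= band[1] & f <= band[2]) |
    (f >= 2 * band[1] & f <= 2 * band[2])
  sum(p[inb]) / sum(p)
}

#' @export
print.rca_pulse_trace <- function(x, ...) {
  cat(sprintf("<rca_pulse_trace> %d samples at %.4g Hz\n",
              length(x$values), x$framerate_hz))
  invisible(x)
}

#' Detect pulse peaks in a trace
#'
#' Local maxima above an adaptive threshold (median + `k_mad` * MAD),
#' separated by at least `min_interval_s` (default 0.33 s, i.e. 180 BPM).
#'
#' @param trace An `rca_pulse_trace` (or numeric vector with
#'   `framerate_hz`).
#' @param min_interval_s Minimum peak separation in seconds.
#' @param k_mad Threshold in MAD units above the median.
#' @param framerate_hz Sampling rate for bare vectors.
#' @return Peak times in seconds (possibly empty).
#' @export
detect_pulse_peaks <- function(trace, min_interval_s = 0.33, k_mad = 2,
                               framerate_hz = NULL) {
  if (inherits(trace, "rca_pulse_trace")) {
    v <- trace$values; fr <- trace$framerate_hz
  } else {
    v <- trace; fr <- framerate_hz
  }
  stopifnot(length(v) > 2 * min_interval_s * fr)
  thr <- stats::median(v) + k_mad * stats::mad(v)
  if (stats::mad(v) == 0 && max(v) == min(v)) return(numeric(0))
  pk <- find_peaks(v, min_dist = max(1L, round(min_interval_s * fr)),
                   min_height = thr)
  (pk - 1) / fr
}

#' Per-beat heart rate from peak times
#'
#' @param peaks Increasing peak times in seconds (>= 2).
#' @return Numeric vector of per-interval rates in BPM.
#' @export
heart_rate <- function(peaks) {
  if (length(peaks) < 2) stop("need at least 2 peaks", call. = FALSE)
  60 / diff(peaks)
}

#' Bland-Altman agreement between two paired series
#'
#' Bias is `mean(a - b)`; the 95% limits of agreement are
#' `bias +- 1.96 * sd(a - b)`.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return An `rca_bland_altman` with `bias`, `loa_low`, `loa_high`, `n`,
#'   and the paired means/differences.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  stopifnot(length(a) >= 2)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd = s, n = length(a),
                 means = (a + b) / 2, differences = d),
            class = "rca_bland_altman")
}

#' @export
print.rca_bland_altman <- function(x, ...) {
  cat(sprintf("<rca_bland_altman> bias %.3g, 95%% LoA [%.3g, %.3g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pulse wave transit time
#'
#' Matches each mechanical-pulse-wave peak to the latest preceding ECG
#' R-peak within `(0, window_s]` and returns the per-beat delays. Unmatched
#' beats are dropped and counted.
#'
#' @param r_peaks R-peak times in seconds.
#' @param mpw_peaks Tissue-deformation peak times in seconds.
#' @param window_s Maximum physiological delay after the R-peak.
#' @return A list with `delays`, `mean`, `sd`, `n`, `dropped`.
#' @export
pwtt <- function(r_peaks, mpw_peaks, window_s = 0.6) {
  delays <- numeric(0)
  used <- logical(length(r_peaks))
  for (tm in mpw_peaks) {
    prev <- which(r_peaks <= tm & tm - r_peaks <= window_s)
    if (length(prev)) {
      k <- prev[length(prev)]
      if (!used[k]) {
        delays <- c(delays, tm - r_peaks[k])
        used[k] <- TRUE
      }
    }
  }
  if (!length(delays)) stop("no pairable beats between the R-peak and ",
                            "pulse trains", call. = FALSE)
  list(delays = delays, mean = mean(delays), sd = stats::sd(delays),
       n = length(delays),
       dropped = length(mpw_peaks) - length(delays))
}

#' Pulse wave velocity
#'
#' Path length divided by the pulse wave transit time; e.g. 0.88 m over
#' 0.214 s gives 4.11 m/s.
#'
#' @param distance_m Heart-to-site path length in metres.
#' @param pwtt_s Transit time in seconds.
#' @return Velocity in m/s.
#' @export
pwv <- function(distance_m, pwtt_s) {
  if (any(distance_m <= 0) || any(pwtt_s <= 0)) {
    stop("distance and transit time must be positive", call. = FALSE)
  }
  distance_m / pwtt_s
}

#' Width at half prominence of detected peaks
#'
#' Per peak, the width of the trace at half its prominence (height above
#' the higher of the two flanking minima), with linear interpolation at the
#' crossings.
#'
#' @param trace An `rca_pulse_trace` or numeric vector.
#' @param peaks Peak times in seconds (defaults to
#'   [detect_pulse_peaks()]).
#' @param framerate_hz Sampling rate for bare vectors.
#' @return Widths in seconds, one per peak.
#' @export
peak_fwhm <- function(trace, peaks = NULL, framerate_hz = NULL) {
  if (inherits(trace, "rca_pulse_trace")) {
    v <- trace$values; fr <- trace$framerate_hz
  } else {
    v <- trace; fr <- framerate_hz
  }
  if (is.null(peaks)) peaks <- detect_pulse_peaks(trace,
                                                  framerate_hz = framerate_hz)
  if (!length(peaks)) return(numeric(0))
  idx <- round(peaks * fr) + 1
  n <- length(v)
  widths <- numeric(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    lo <- if (q == 1) 1 else idx[q - 1]
    hi <- if (q == length(idx)) n else idx[q + 1]
    base <- max(min(v[lo:i]), min(v[i:hi]))
    half <- base + (v[i] - base) / 2
    il <- i
    while (il > 1 && v[il - 1] > half) il <- il - 1
    xl <- if (il == 1) 1 else il - 1 +
      (half - v[il - 1]) / (v[il] - v[il - 1])
    ir <- i
    while (ir < n && v[ir + 1] > half) ir <- ir + 1
    xr <- if (ir == n) n else ir +
      (half - v[ir]) / (v[ir + 1] - v[ir])
    widths[q] <- (xr - xl) / fr
  }
  widths
}
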