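#' Clutter filter specification
#'
#' SVD clutter rejection removes the top `low_fraction` of singular modes
#' (slow, high-energy tissue) and the last `high_count` modes (electronic
#' noise), the rule used in vivo: the first 15% of modes and the last 50.
#'
#' The fractional rule is calibrated to in vivo tissue, whose clutter rank
#' grows with the ensemble; for strictly static phantoms the clutter rank
#' is bounded, and `low_count` can fix the number of removed low modes
#' instead.
#'
#' @param low_fraction Fraction of modes removed from the top.
#' @param high_count Number of modes removed from the tail.
#' @param low_count Optional absolute number of low modes to remove,
#'   overriding `low_fraction`.
#' @return An `rca_clutter_spec`.
#' @export
clutter_filter_spec <- function(low_fraction = 0.15, high_count = 50L,
                                low_count = NULL) {
  stopifnot(low_fraction >= 0, low_fraction < 1, high_count >= 0)
  structure(list(low_fraction = low_fraction,
                 high_count = as.integer(high_count),
                 low_count = if (!is.null(low_count)) as.integer(low_count)),
            class = "rca_clutter_spec")
}

#' SVD clutter filtering of an IQ series
#'
#' Decomposes the Casorati matrix (voxels x slow time), zeroes the first
#' `ceil(low_fraction * n_slow)` and last `high_count` singular components,
#' and reconstructs the blood signal. The singular-value spectrum is
#' returned for diagnostics. The filter is an orthogonal projection:
#' applying it twice equals applying it once.
#'
#' @param series An `rca_iq_series`.
#' @param spec An [clutter_filter_spec()].
#' @return The filtered `rca_iq_series`, with attributes
#'   `singular_values` and `modes_removed`.
#' @export
svd_clutter_filter <- function(series, spec = clutter_filter_spec()) {
  stopifnot(inherits(series, "rca_iq_series"))
  d <- dim(series$data)
  nt <- d[4]
  n_low <- spec$low_count %||% ceiling(spec$low_fraction * nt)
  min_nt <- spec$high_count + n_low + 1
  if (nt < min_nt) {
    stop("ensemble of ", nt, " frames too short for this filter; at least ",
         spec$high_count, " + ceil(", spec$low_fraction, " * n) + 1 frames ",
         "are required", call. = FALSE)
  }
  C <- matrix(series$data, prod(d[1:3]), nt)
  # right singular vectors from the (Hermitian) nt x nt Gram matrix
  G <- crossprod(Conj(C), C)
  eg <- eigen(G, symmetric = TRUE)
  sv <- sqrt(pmax(Re(eg$values), 0))
  keep <- setdiff(seq_len(nt),
                  c(seq_len(n_low), seq(nt - spec$high_count + 1, nt)))
  V <- eg$vectors[, keep, drop = FALSE]
  Cf <- C %*% V %*% Conj(t(V))
  out <- series
  out$data <- array(Cf, d)
  out$filtered <- TRUE
  attr(out, "singular_values") <- sv
  attr(out, "modes_removed") <- list(low = seq_len(n_low),
                                     high = seq(nt - spec$high_count + 1, nt))
  attr(out, "basis") <- V # retained temporal subspace (projector basis)
  out
}

#' Re-apply a retained clutter-filter subspace
#'
#' Projects a series onto the temporal basis returned by a previous
#' [svd_clutter_filter()] call (attribute `basis`). The projection is
#' idempotent; note that re-running the rank-counting filter itself is not,
#' since mode indices shift once components are zeroed.
#'
#' @param series An `rca_iq_series`.
#' @param basis Complex matrix of retained temporal modes (columns).
#' @return The projected series.
#' @export
project_clutter_basis <- function(series, basis) {
  d <- dim(series$data)
  C <- matrix(series$data, prod(d[1:3]), d[4])
  out <- series
  out$data <- array(C %*% basis %*% Conj(t(basis)), d)
  out$filtered <- TRUE
  out
}

#' Power Doppler volume
#'
#' Mean slow-time power per voxel of a clutter-filtered series; the standard
#' proxy for local blood volume.
#'
#' @param filtered An `rca_iq_series` (clutter-filtered).
#' @return An `rca_volume`.
#' @export
power_doppler <- function(filtered) {
  stopifnot(inherits(filtered, "rca_iq_series"))
  d <- dim(filtered$data)
  m <- matrix(Mod(filtered$data)^2, prod(d[1:3]), d[4])
  new_volume(array(rowMeans(m), d[1:3]), filtered$grid)
}

#' Signed power Doppler
#'
#' Power Doppler signed by the direction of the mean Doppler shift, taken
#' from the phase of the lag-1 slow-time autocorrelation. Flow towards the
#' array (decreasing depth) is positive.
#'
#' @param filtered Clutter-filtered `rca_iq_series`.
#' @return An `rca_volume` of signed power.
#' @export
signed_power_doppler <- function(filtered) {
  stopifnot(inherits(filtered, "rca_iq_series"))
  d <- dim(filtered$data)
  M <- matrix(filtered$data, prod(d[1:3]), d[4])
  r1 <- rowSums(M[, -1, drop = FALSE] * Conj(M[, -d[4], drop = FALSE]))
  pd <- rowMeans(Mod(M)^2)
  new_volume(array(sign(Arg(r1)) * pd, d[1:3]), filtered$grid)
}

#' Fit the skin surface and mask shallow voxels
#'
#' Detects the skin interface per (x, y) column as the maximum axial
#' gradient of the linear envelope of a B-mode volume, fits a least-squares
#' polynomial surface z(x, y) of the given order, and returns a mask that
#' zeroes all voxels above (shallower than) the surface.
#'
#' @param bm A B-mode `rca_volume` in dB.
#' @param poly_order Polynomial surface order (0 = flat plane).
#' @param min_frac Minimum fraction of columns with a detected interface.
#' @return List with `surface` (nx x ny matrix of z in metres), `mask`
#'   (logical array, TRUE = keep), and the detected points.
#' @export
fit_skin_surface <- function(bm, poly_order = 2L, min_frac = 0.3) {
  stopifnot(inherits(bm, "rca_volume"))
  v <- 10^(bm$values / 20)
  g <- bm$grid
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  if (nz < 3) stop("need at least 3 axial samples", call. = FALSE)
  zi <- matrix(NA_real_, nx, ny)
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      prof <- v[ix, iy, ]
      dgr <- diff(prof)
      k <- which.max(dgr)
      # require a real interface: a significant rise above the noise floor
      if (max(prof) > 10^(-40 / 20) && dgr[k] > 0.05 * max(prof)) {
        zi[ix, iy] <- g$z[k + 1]
      }
    }
  }
  det <- which(!is.na(zi), arr.ind = TRUE)
  if (nrow(det) < min_frac * nx * ny) {
    stop("skin interface detected in fewer than ", round(100 * min_frac),
         "% of columns: degenerate surface fit", call. = FALSE)
  }
  df <- data.frame(x = g$x[det[, 1]], y = g$y[det[, 2]],
                   z = zi[!is.na(zi)])
  fit <- if (poly_order == 0) {
    stats::lm(z ~ 1, data = df)
  } else {
    stats::lm(z ~ polym(x, y, degree = poly_order, raw = TRUE), data = df)
  }
  newd <- expand.grid(x = g$x, y = g$y)
  zs <- matrix(stats::predict(fit, newdata = newd), nx, ny)
  mask <- array(TRUE, c(nx, ny, nz))
  for (iz in seq_len(nz)) mask[, , iz] <- g$z[iz] >= zs
  list(surface = zs, mask = mask, points = df, fit = fit)
}

#' Apply a skin mask to an IQ series or volume
#'
#' @param x An `rca_iq_series` or `rca_volume`.
#' @param mask Logical array from [fit_skin_surface()] (TRUE = keep).
#' @return The masked object (masked voxels set to zero).
#' @export
apply_skin_mask <- function(x, mask) {
  if (inherits(x, "rca_iq_series")) {
    d <- dim(x$data)
    x$data <- x$data * array(rep(as.numeric(mask), d[4]), d)
  } else if (inherits(x, "rca_volume")) {
    x$values <- x$values * as.numeric(mask)
  } else stop("unsupported type", call. = FALSE)
  x
}

#' Spectral Doppler of a small ROI
#'
#' Short-time Fourier transform (Hann window, 50% overlap) of the slow-time
#' signal of each voxel in a cubic ROI, magnitudes averaged over the ROI.
#' Doppler frequency maps to axial velocity `v = c * f_d / (2 * f0)`; the
#' velocity axis spans the slow-time Nyquist range
#' `+- c * (framerate / 2) / (2 * f0)`.
#'
#' @param filtered Clutter-filtered `rca_iq_series`.
#' @param roi_center Voxel index `c(ix, iy, iz)` of the ROI centre.
#' @param roi_half Half-width of the cubic ROI in voxels (1 = 3x3x3).
#' @param window STFT window length in frames.
#' @param overlap Fractional window overlap.
#' @param c Speed of sound, m/s.
#' @return An `rca_spectral` with `magnitude` [velocity_bin, time],
#'   `velocity` (m/s) and `time` (s) axes.
#' @export
spectral_doppler <- function(filtered, roi_center, roi_half = 1L,
                             window = 30L, overlap = 0.5,
                             c = 1480) {
  stopifnot(inherits(filtered, "rca_iq_series"))
  d <- dim(filtered$data)
  rc <- as.integer(roi_center)
  if (any(rc - roi_half < 1) || any(rc + roi_half > d[1:3])) {
    stop("ROI extends outside the volume grid", call. = FALSE)
  }
  fr <- filtered$framerate_hz
  hop <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1, d[4] - window + 1, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(window) - 1) / (window - 1)))
  nb <- window
  mag <- matrix(0, nb, length(starts))
  idx <- expand.grid(ix = (rc[1] - roi_half):(rc[1] + roi_half),
                     iy = (rc[2] - roi_half):(rc[2] + roi_half),
                     iz = (rc[3] - roi_half):(rc[3] + roi_half))
  for (q in seq_len(nrow(idx))) {
    s <- filtered$data[idx$ix[q], idx$iy[q], idx$iz[q], ]
    for (w in seq_along(starts)) {
      seg <- s[starts[w]:(starts[w] + window - 1)] * win
      S <- stats::fft(seg)
      # fftshift so negative Doppler frequencies come first
      S <- c(S[(floor(nb / 2) + 1):nb], S[1:floor(nb / 2)])
      mag[, w] <- mag[, w] + Mod(S)
    }
  }
  mag <- mag / nrow(idx)
  fd <- ((seq_len(nb) - 1) - floor(nb / 2)) * fr / nb
  structure(list(magnitude = mag, velocity = c * fd / (2 * filtered$f0),
                 time = (starts - 1 + window / 2) / fr,
                 window = window, framerate_hz = fr),
            class = "rca_spectral")
}

#' Envelope velocity of a spectral Doppler display
#'
#' Per time column, the velocity below which `percentile` of the spectral
#' power lies (a percentile maximum-frequency envelope).
#'
#' @param sp An `rca_spectral`.
#' @param percentile Power percentile in (0, 1).
#' @return Tibble with `time` and `velocity`.
#' @export
spectral_envelope <- function(sp, percentile = 0.95) {
  stopifnot(inherits(sp, "rca_spectral"))
  env <- apply(sp$magnitude^2, 2, function(p) {
    cs <- cumsum(p) / sum(p)
    sp$velocity[which(cs >= percentile)[1]]
  })
  tibble::tibble(time = sp$time, velocity = env)
}

#' Resistive index of a velocity waveform
#'
#' Per cardiac cycle, `(peak systolic - end diastolic) / peak systolic`,
#' averaged over cycles. Cycles are delimited by systolic peaks; with fewer
#' than two detectable peaks the whole trace is treated as one cycle.
#'
#' @param v Velocity waveform (numeric).
#' @param framerate_hz Sampling rate of the waveform.
#' @param min_interval_s Minimum peak separation for cycle detection.
#' @return Mean RI, with per-cycle values as attribute `per_cycle`.
#' @export
resistive_index <- function(v, framerate_hz = NULL, min_interval_s = 0.33) {
  if (max(v) <= 0) stop("non-positive peak velocity", call. = FALSE)
  if (max(v) == min(v)) return(0)
  peaks <- if (!is.null(framerate_hz)) {
    find_peaks(v, min_dist = max(1L, round(min_interval_s * framerate_hz)),
               min_height = min(v) + 0.5 * (max(v) - min(v)))
  } else integer(0)
  ri <- if (length(peaks) >= 2) {
    vapply(seq_len(length(peaks) - 1), function(i) {
      seg <- v[peaks[i]:peaks[i + 1]]
      (max(seg) - min(seg)) / max(seg)
    }, 0)
  } else {
    (max(v) - min(v)) / max(v)
  }
  out <- mean(ri)
  attr(out, "per_cycle") <- ri
  out
}

# indices of local maxima above min_height, separated by >= min_dist,
# greedily retained in decreasing height order
find_peaks <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}
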