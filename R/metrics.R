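#' -3 dB full width at half maximum of an intensity profile
#'
#' Extracts the 1-D profile through the intensity peak along one axis,
#' refines the peak by parabolic interpolation and locates the half-maximum
#' crossings by linear interpolation between samples.
#'
#' @param volume `rca_volume` (intensity, i.e. squared envelope) or a bare
#'   array with `grid`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param grid Optional [voxel_grid()] for bare arrays.
#' @return Width in metres.
#' @export
profile_fwhm <- function(volume, axis = c("x", "y", "z"), grid = NULL) {
  axis <- match.arg(axis)
  if (inherits(volume, "rca_volume")) {
    grid <- volume$grid
    volume <- volume$values
  }
  pk <- which(volume == max(volume), arr.ind = TRUE)[1, ]
  prof <- switch(axis,
                 x = volume[, pk[2], pk[3]],
                 y = volume[pk[1], , pk[3]],
                 z = volume[pk[1], pk[2], ])
  coord <- grid[[axis]]
  fwhm_1d(coord, prof)
}

# half-max width of a sampled profile: cubic-spline oversampling (16x)
# decouples the estimate from the voxel grid, crossings by linear
# interpolation on the dense profile
fwhm_1d <- function(coord, prof) {
  sp <- stats::spline(coord, prof, n = 16 * length(coord), method = "fmm")
  x <- sp$x; p <- sp$y
  i0 <- which.max(p)
  half <- p[i0] / 2
  il <- i0
  while (il > 1 && p[il - 1] > half) il <- il - 1
  ir <- i0
  n <- length(p)
  while (ir < n && p[ir + 1] > half) ir <- ir + 1
  if ((il == 1 && p[1] > half) || (ir == n && p[n] > half)) {
    stop("profile does not drop below half maximum within the field of view",
         call. = FALSE)
  }
  xl <- x[il - 1] + (x[il] - x[il - 1]) *
    (half - p[il - 1]) / (p[il] - p[il - 1])
  xr <- x[ir] + (x[ir + 1] - x[ir]) *
    (half - p[ir]) / (p[ir + 1] - p[ir])
  xr - xl
}

# first local minima outward from the peak along each axis; returns index
# ranges delimiting the main lobe
main_lobe_box <- function(volume, pk) {
  lims <- matrix(0L, 3, 2)
  for (a in 1:3) {
    prof <- switch(a,
                   volume[, pk[2], pk[3]],
                   volume[pk[1], , pk[3]],
                   volume[pk[1], pk[2], ])
    i0 <- pk[a]; n <- length(prof)
    il <- i0
    while (il > 1 && prof[il - 1] < prof[il]) il <- il - 1
    ir <- i0
    while (ir < n && prof[ir + 1] < prof[ir]) ir <- ir + 1
    lims[a, ] <- c(il, ir)
  }
  lims
}

#' Side- and grating-lobe levels of a PSF volume
#'
#' Side lobes are measured on the lateral intensity profiles through the
#' peak (the PSF profiles): along each lateral axis the main lobe extends
#' to the first local minima outward from the peak, and the side-lobe level
#' is the maximum beyond them, in dB relative to the peak, worst axis. If a
#' grating sine band is supplied (see [grating_sine_band()]), the grating
#' level is the maximum over voxels of the full volume whose direction sine
#' from the peak's lateral position falls in the band; those positions are
#' excluded from the side-lobe search.
#'
#' @param volume Intensity `rca_volume` or array.
#' @param grid [voxel_grid()] for bare arrays.
#' @param grating_band Optional numeric range of |sin(angle)| for the
#'   grating annulus.
#' @return List with `side_db`, `grating_db` (NA when no band given), and
#'   the per-axis main-lobe index ranges.
#' @export
lobe_levels <- function(volume, grid = NULL, grating_band = NULL) {
  if (inherits(volume, "rca_volume")) {
    grid <- volume$grid
    volume <- volume$values
  }
  pk <- which(volume == max(volume), arr.ind = TRUE)[1, ]
  peak <- max(volume)
  lims <- main_lobe_box(volume, pk)

  side_max <- 0
  found <- FALSE
  for (a in 1:2) { # lateral profiles through the peak
    prof <- if (a == 1) volume[, pk[2], pk[3]] else volume[pk[1], , pk[3]]
    coord <- if (a == 1) grid$x else grid$y
    c0 <- coord[pk[a]]
    out <- seq_along(prof) < lims[a, 1] | seq_along(prof) > lims[a, 2]
    if (!is.null(grating_band)) {
      s <- abs(coord - c0) / sqrt((coord - c0)^2 + grid$z[pk[3]]^2)
      out <- out & !(s >= grating_band[1] & s <= grating_band[2])
    }
    if (any(out)) {
      side_max <- max(side_max, max(prof[out]))
      found <- TRUE
    }
  }
  if (!found) {
    # no first minimum within the FOV: either the main lobe fills the
    # lateral extent (unmeasurable) or the profile decays monotonically
    # without side lobes
    pmin_ <- min(volume[, pk[2], pk[3]], volume[pk[1], , pk[3]])
    if (pmin_ > peak / 2) {
      stop("main lobe covers the whole lateral field of view; no side-lobe ",
           "region", call. = FALSE)
    }
    side_max <- 0
  }
  side_db <- 10 * log10(side_max / peak)

  grating_db <- NA_real_
  if (!is.null(grating_band)) {
    x0 <- grid$x[pk[1]]; y0 <- grid$y[pk[2]]
    grat <- array(FALSE, dim(volume))
    sx <- outer(abs(grid$x - x0), grid$z,
                function(dx, z) dx / sqrt(dx^2 + z^2))
    sy <- outer(abs(grid$y - y0), grid$z,
                function(dy, z) dy / sqrt(dy^2 + z^2))
    inx <- sx >= grating_band[1] & sx <= grating_band[2]
    iny <- sy >= grating_band[1] & sy <= grating_band[2]
    for (iz in seq_along(grid$z)) {
      grat[inx[, iz], , iz] <- TRUE
      grat[, iny[, iz], iz] <- TRUE
    }
    if (any(grat)) grating_db <- 10 * log10(max(volume[grat]) / peak)
  }
  list(side_db = side_db, grating_db = grating_db, main_lobe = lims)
}

#' Predicted grating-lobe sine band of a steered scheme
#'
#' For a steered transmission at angle theta on a pitch-p array, grating
#' replicas appear at `sin(theta_g) = sin(theta) +- lambda / pitch` when
#' that value is in (-1, 1). The band returned is the union over the
#' scheme's angles, widened by `tol`.
#'
#' @param scheme An `rca_scheme`.
#' @param wavelength Wavelength in metres.
#' @param tol Band widening in sine units.
#' @return `c(smin, smax)` of |sin|, or `NULL` when no propagating grating
#'   lobe exists.
#' @export
grating_sine_band <- function(scheme, wavelength, tol = 0.05) {
  ratio <- wavelength / scheme$array$pitch
  angs <- unique(vapply(scheme$events, function(e) e$steer_angle_deg, 0))
  s <- sin(angs * pi / 180)
  cand <- c(s + ratio, s - ratio)
  cand <- abs(cand[abs(cand) < 1])
  if (!length(cand)) return(NULL)
  c(max(min(cand) - tol, 0), min(max(cand) + tol, 0.999))
}

#' Contrast-to-noise ratio of a power-Doppler volume
#'
#' `10 * log10(mean(PD in vessel) / sd(PD in background))`.
#'
#' @param pd `rca_volume` or array of power-Doppler values.
#' @param vessel_mask,background_mask Disjoint logical arrays.
#' @return CNR in dB.
#' @export
cnr <- function(pd, vessel_mask, background_mask) {
  if (inherits(pd, "rca_volume")) pd <- pd$values
  stopifnot(any(vessel_mask), any(background_mask),
            !any(vessel_mask & background_mask))
  s <- stats::sd(pd[background_mask])
  if (s == 0) stop("zero background standard deviation", call. = FALSE)
  10 * log10(mean(pd[vessel_mask]) / s)
}

#' Signal-to-noise ratio of a power-Doppler volume
#'
#' `10 * log10(mean(PD in signal) / mean(PD in noise))`.
#'
#' @param pd `rca_volume` or array.
#' @param signal_mask,noise_mask Nonempty logical arrays.
#' @return SNR in dB.
#' @export
snr <- function(pd, signal_mask, noise_mask) {
  if (inherits(pd, "rca_volume")) pd <- pd$values
  stopifnot(any(signal_mask), any(noise_mask))
  den <- mean(pd[noise_mask])
  if (den == 0) stop("zero noise power", call. = FALSE)
  10 * log10(mean(pd[signal_mask]) / den)
}

#' PSF quality report
#'
#' Per-axis -3 dB FWHM plus side- and grating-lobe levels of an intensity
#' PSF volume, as a one-row tibble.
#'
#' @param volume Intensity `rca_volume`.
#' @param grating_band Optional |sin| band from [grating_sine_band()].
#' @param scheme_name Label recorded in the report.
#' @return A `tibble` with class `rca_psf_report`.
#' @export
psf_report <- function(volume, grating_band = NULL, scheme_name = "") {
  ll <- lobe_levels(volume, grating_band = grating_band)
  out <- tibble::tibble(
    scheme = scheme_name,
    fwhm_x = profile_fwhm(volume, "x"),
    fwhm_y = profile_fwhm(volume, "y"),
    fwhm_z = profile_fwhm(volume, "z"),
    side_lobe_db = ll$side_db,
    grating_lobe_db = ll$grating_db
  )
  class(out) <- c("rca_psf_report", class(out))
  out
}

#' Intensity (squared-envelope) volume of a beamformed frame
#'
#' @param series An `rca_iq_series` (or complex array).
#' @param frame Frame index.
#' @param grid Grid for bare arrays.
#' @return `rca_volume` of |v|^2.
#' @export
intensity_volume <- function(series, frame = 1L, grid = NULL) {
  if (inherits(series, "rca_iq_series")) {
    grid <- series$grid
    v <- series$data[, , , frame]
  } else v <- series
  new_volume(Mod(v)^2, grid)
}
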