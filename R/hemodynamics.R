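#' Peripheral blood volume series from power-Doppler frames
#'
#' Percent change of the ROI-mean power Doppler relative to the baseline
#' mean: `100 * (mean_roi PD(t) - B) / B`.
#'
#' @param pd_frames Power-Doppler values: a `[nx, ny, nz, n_t]` array, or a
#'   voxels x time matrix.
#' @param roi Logical mask over voxels (array or vector); default all.
#' @param baseline_window Frame indices of the pre-stimulus baseline.
#' @return Tibble with `frame` and `pbv_pct`, class `rca_pbv`.
#' @export
pbv_series <- function(pd_frames, roi = NULL, baseline_window = NULL) {
  d <- dim(pd_frames)
  m <- if (length(d) == 4) matrix(pd_frames, prod(d[1:3]), d[4]) else
    as.matrix(pd_frames)
  if (is.null(roi)) roi <- rep(TRUE, nrow(m))
  tr <- colMeans(m[as.logical(roi), , drop = FALSE])
  if (is.null(baseline_window)) baseline_window <- seq_len(max(1, ncol(m) %/% 4))
  B <- mean(tr[baseline_window])
  if (B == 0) stop("zero baseline power", call. = FALSE)
  out <- tibble::tibble(frame = seq_along(tr),
                        pbv_pct = 100 * (tr - B) / B)
  class(out) <- c("rca_pbv", class(out))
  attr(out, "baseline") <- B
  out
}

#' Tri-level stimulus regressor
#'
#' 0 during baseline, -1 during the cold immersion, +1 during the hot
#' immersion, sampled at the protocol's Doppler volume rate (one
#' correlation then captures both phases; a 0/1 hot-only coding is also
#' available).
#'
#' @param protocol A [stimulus_protocol()].
#' @param coding `"trilevel"` or `"hot_only"`.
#' @return Numeric series, one value per Doppler frame.
#' @export
stimulus_regressor <- function(protocol, coding = c("trilevel", "hot_only")) {
  coding <- match.arg(coding)
  dt <- 1 / protocol$doppler_rate_hz
  total <- protocol$baseline_s + protocol$cold_s + protocol$hot_s
  t <- seq(0, total - dt, by = dt)
  r <- numeric(length(t))
  cold <- t >= protocol$baseline_s &
    t < protocol$baseline_s + protocol$cold_s
  hot <- t >= protocol$baseline_s + protocol$cold_s
  if (coding == "trilevel") r[cold] <- -1
  r[hot] <- 1
  r
}

#' Fisher z-score map of stimulus correlation
#'
#' Per voxel, the Pearson correlation of the PD time course with the
#' stimulus regressor, Fisher-transformed to an approximately unit-normal
#' statistic `z = atanh(r) * sqrt(n - 3)`. Constant voxels get z = 0 and
#' are counted in attribute `flagged`.
#'
#' @param pd_series `[nx, ny, nz, n_t]` array or voxels x time matrix.
#' @param regressor Stimulus series of length `n_t`.
#' @return Array (or vector) of z-scores.
#' @export
zscore_map <- function(pd_series, regressor) {
  d <- dim(pd_series)
  m <- if (length(d) == 4) matrix(pd_series, prod(d[1:3]), d[4]) else
    as.matrix(pd_series)
  n <- ncol(m)
  stopifnot(n >= 4, length(regressor) == n)
  xc <- sweep(m, 1, rowMeans(m))
  yc <- regressor - mean(regressor)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.numeric(xc %*% yc) / (sx * sy)
  flagged <- sx == 0
  r[flagged] <- 0
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  z <- atanh(r) * sqrt(n - 3)
  out <- if (length(d) == 4) array(z, d[1:3]) else z
  attr(out, "flagged") <- sum(flagged)
  out
}

#' Bonferroni-corrected z threshold
#'
#' The number of independent tests is the imaging volume divided by the PSF
#' volume; the threshold is the one-tailed inverse-normal quantile
#' `qnorm(1 - alpha / N)`, applied to |z| as a multi-one-tailed rule.
#'
#' @param alpha Family-wise error level.
#' @param fov_volume_mm3 Imaging volume in cubic millimetres.
#' @param psf_volume_mm3 PSF (-3 dB ellipsoid) volume in cubic millimetres.
#' @return z threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.001, fov_volume_mm3,
                                 psf_volume_mm3) {
  stopifnot(fov_volume_mm3 > 0, psf_volume_mm3 > 0)
  N <- fov_volume_mm3 / psf_volume_mm3
  if (alpha / N >= 1) {
    warning("alpha / N >= 1: threshold degenerates to 0", call. = FALSE)
    return(0)
  }
  stats::qnorm(1 - alpha / N)
}

#' -3 dB ellipsoid volume of a PSF
#'
#' `(4/3) pi * (fwhm_x/2) * (fwhm_y/2) * (fwhm_z/2)`, the per-test volume
#' used for Bonferroni counting.
#'
#' @param fwhm_m Per-axis FWHM in metres (length 3).
#' @return Volume in cubic millimetres.
#' @export
psf_volume_mm3 <- function(fwhm_m) {
  stopifnot(length(fwhm_m) == 3, all(fwhm_m > 0))
  4 / 3 * pi * prod(fwhm_m * 1e3 / 2)
}

#' Hemodynamic response fit container
#'
#' Gamma-difference kernel `h(tau) = dgamma(tau; a1, b1) - w * dgamma(tau;
#' a2, b2)` (shape/scale), convolved with the stimulus step. The rise time
#' is the kernel mode (stimulus to response-rate maximum); the duration is
#' the SD of the normalised positive part of the kernel.
#'
#' @param a1,b1 Shape/scale of the positive gamma.
#' @param a2,b2 Shape/scale of the negative gamma.
#' @param w Negative-lobe weight in `[0, 1]`.
#' @param amplitude Response gain.
#' @param baseline Offset.
#' @return An `rca_hrf_fit`.
#' @export
hrf_fit <- function(a1 = 4.68, b1 = 3.88, a2 = 6, b2 = 3, w = 0,
                    amplitude = 1, baseline = 0) {
  stopifnot(a1 > 0, b1 > 0, a2 > 0, b2 > 0, w >= 0)
  obj <- structure(
    list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, w = w,
         amplitude = amplitude, baseline = baseline, rss = NA_real_),
    class = "rca_hrf_fit")
  k <- hrf_kernel_metrics(obj)
  obj$rise_time_s <- k$rise
  obj$duration_sd_s <- k$sd
  obj
}

hrf_kernel <- function(fit, tau) {
  stats::dgamma(tau, shape = fit$a1, scale = fit$b1) -
    fit$w * stats::dgamma(tau, shape = fit$a2, scale = fit$b2)
}

hrf_kernel_metrics <- function(fit, t_max = 120, n = 4801) {
  tau <- seq(0, t_max, length.out = n)
  h <- hrf_kernel(fit, tau)
  rise <- tau[which.max(h)]
  hp <- pmax(h, 0)
  wgt <- hp / sum(hp)
  mu <- sum(tau * wgt)
  list(rise = rise, sd = sqrt(sum((tau - mu)^2 * wgt)))
}

#' @export
print.rca_hrf_fit <- function(x, ...) {
  cat(sprintf(
    "<rca_hrf_fit> rise %.2f s, duration %.2f s, amplitude %.3g, baseline %.3g\n",
    x$rise_time_s, x$duration_sd_s, x$amplitude, x$baseline))
  invisible(x)
}

#' Model response of an HRF to a stimulus series
#'
#' Discrete causal convolution of the stimulus with the gamma-difference
#' kernel, scaled by the sample interval, plus baseline: for a unit step
#' this is the cumulative integral of the kernel (a cumulative difference
#' of gammas), which plateaus at `baseline + amplitude` when `w = 0`.
#'
#' @param t Uniform time grid in seconds.
#' @param fit An [hrf_fit()].
#' @param stimulus Step/stimulus series on `t`.
#' @return Model series on `t`.
#' @export
gamma_diff_response <- function(t, fit, stimulus) {
  stopifnot(length(t) == length(stimulus))
  dt <- diff(t)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("time grid must be uniform", call. = FALSE)
  }
  dt <- if (length(dt)) dt[1] else 1
  h <- hrf_kernel(fit, (seq_along(t) - 1) * dt)
  conv <- stats::convolve(stimulus, rev(h), type = "open")[seq_along(t)]
  fit$baseline + fit$amplitude * conv * dt
}

#' Fit a gamma-difference hemodynamic response
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start with seeded
#' jitter) of `baseline + amplitude * (step (x) h)` to a PBV series under
#' the thermal protocol. The fit window starts at the hot-stimulus onset;
#' the pre-cold baseline fixes the starting offset. Rise time and duration
#' are recomputed from the fitted kernel.
#'
#' @param pbv PBV series (fractional or percent; fitted as given), one
#'   value per Doppler frame.
#' @param protocol A [stimulus_protocol()].
#' @param init Optional initial [hrf_fit()].
#' @param n_starts Number of jittered starts.
#' @param seed Integer seed.
#' @param fit_w Also fit the negative lobe (default FALSE: single-gamma
#'   kernel).
#' @return Fitted `rca_hrf_fit` with residual sum of squares in `rss`.
#' @export
fit_hrf <- function(pbv, protocol = stimulus_protocol(), init = NULL,
                    n_starts = 5L, seed = 1L, fit_w = FALSE) {
  dt <- 1 / protocol$doppler_rate_hz
  total <- protocol$baseline_s + protocol$cold_s + protocol$hot_s
  t <- seq(0, total - dt, by = dt)
  stopifnot(length(pbv) == length(t))
  t_hot <- protocol$baseline_s + protocol$cold_s
  base_idx <- t < protocol$baseline_s
  b0 <- mean(pbv[base_idx])
  sel <- t >= t_hot
  ts <- t[sel] - t_hot
  ys <- pbv[sel]
  amp0 <- max(ys) - b0
  if (is.null(init)) init <- hrf_fit(amplitude = max(amp0, 1e-6),
                                     baseline = b0)
  model <- function(a1, b1, w, a2, b2, amplitude, baseline) {
    f <- list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, w = w)
    baseline + amplitude * (stats::pgamma(ts, shape = a1, scale = b1) -
                              w * stats::pgamma(ts, shape = a2, scale = b2))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    jit <- if (k == 1) c(1, 1) else exp(stats::rnorm(2, 0, 0.3))
    st <- list(a1 = init$a1 * jit[1], b1 = init$b1 * jit[2],
               amplitude = init$amplitude, baseline = init$baseline)
    lw <- c(a1 = 1.05, b1 = 0.05, amplitude = -Inf, baseline = -Inf)
    up <- c(a1 = 200, b1 = 100, amplitude = Inf, baseline = Inf)
    if (fit_w) {
      st <- c(st, list(w = max(init$w, 0.1), a2 = init$a2, b2 = init$b2))
      lw <- c(lw, w = 0, a2 = 1.05, b2 = 0.05)
      up <- c(up, w = 1, a2 = 200, b2 = 100)
    }
    fml <- if (fit_w) {
      ys ~ model(a1, b1, w, a2, b2, amplitude, baseline)
    } else {
      ys ~ model(a1, b1, 0, 2, 1, amplitude, baseline)
    }
    fit <- try(minpack.lm::nlsLM(
      fml, start = st, lower = lw, upper = up,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("no start converged in the HRF fit", call. = FALSE)
  cf <- as.list(stats::coef(best$fit))
  out <- hrf_fit(a1 = cf$a1, b1 = cf$b1,
                 a2 = if (fit_w) cf$a2 else init$a2,
                 b2 = if (fit_w) cf$b2 else init$b2,
                 w = if (fit_w) cf$w else 0,
                 amplitude = cf$amplitude, baseline = cf$baseline)
  out$rss <- best$rss
  out$n <- length(ys)
  out
}

#' Normality-checked two-sample comparison
#'
#' Shapiro-Wilk on each sample, then a paired t test (`paired = TRUE`) or a
#' Welch test; thin contracts over the standard routines.
#'
#' @param x,y Numeric samples (n >= 3 each).
#' @param paired Paired comparison (requires equal lengths).
#' @return One-row tibble with normality p-values, the test statistic,
#'   degrees of freedom and p-value.
#' @export
group_stats <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (paired && length(x) != length(y)) {
    stop("paired samples must have equal lengths", call. = FALSE)
  }
  swx <- stats::shapiro.test(x)$p.value
  swy <- stats::shapiro.test(y)$p.value
  if (paired && stats::sd(x - y) == 0) {
    # identical pairs: no variability, trivially no difference
    return(tibble::tibble(test = "paired t", shapiro_p_x = swx,
                          shapiro_p_y = swy, statistic = 0,
                          df = length(x) - 1, p_value = 1,
                          mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = FALSE)
  tibble::tibble(
    test = if (paired) "paired t" else "Welch",
    shapiro_p_x = swx, shapiro_p_y = swy,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_x = mean(x), mean_y = mean(y))
}
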