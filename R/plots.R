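#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pulse trace
#'
#' @param object An `rca_pulse_trace`.
#' @param peaks Optional peak times to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rca_pulse_trace <- function(object, peaks = NULL, ...) {
  df <- tidy.rca_pulse_trace(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "deformation (a.u.)")
  if (!is.null(peaks) && length(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = peaks, linetype = "dashed",
                                 colour = "firebrick", alpha = 0.5)
  }
  p
}

#' Bland-Altman plot
#'
#' @param object An `rca_bland_altman`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rca_bland_altman <- function(object, ...) {
  df <- tidy.rca_bland_altman(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of methods", y = "difference")
}

#' Spectral Doppler display
#'
#' @param object An `rca_spectral`.
#' @param dynamic_db Display dynamic range in dB.
#' @param ... Unused.
#' @return A ggplot raster of the spectrogram.
#' @export
autoplot.rca_spectral <- function(object, dynamic_db = 40, ...) {
  m <- object$magnitude
  db <- 20 * log10(pmax(m, max(m) * 1e-6) / max(m))
  df <- expand.grid(velocity = object$velocity, time = object$time)
  df$db <- as.numeric(pmax(db, -dynamic_db))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$velocity * 1e3,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "axial velocity (mm/s)")
}

#' Maximum-intensity projection of a volume
#'
#' @param volume An `rca_volume`.
#' @param axis Projection axis (`"x"`, `"y"` or `"z"`).
#' @param log_db Display in dB relative to the maximum.
#' @return A ggplot raster.
#' @export
plot_mip <- function(volume, axis = c("z", "x", "y"), log_db = FALSE) {
  axis <- match.arg(axis)
  g <- volume$grid
  ai <- match(axis, c("x", "y", "z"))
  m <- apply(volume$values, setdiff(1:3, ai), max)
  if (log_db) m <- 10 * log10(pmax(m, max(m) * 1e-6) / max(m))
  axes <- setdiff(c("x", "y", "z"), axis)
  df <- expand.grid(a = g[[axes[1]]] * 1e3, b = g[[axes[2]]] * 1e3)
  df$v <- as.numeric(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (log_db) "dB" else "power") +
    ggplot2::labs(x = paste0(axes[1], " (mm)"), y = paste0(axes[2], " (mm)"))
}

#' PBV time-course plot
#'
#' @param object An `rca_pbv` tibble.
#' @param rate_hz Doppler volume rate for the time axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rca_pbv <- function(object, rate_hz = 0.5, ...) {
  df <- data.frame(time = (object$frame - 1) / rate_hz,
                   pbv = object$pbv_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pbv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "PBV change (%)")
}
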