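#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HRF fit
#'
#' @param x An `rca_hrf_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates.
#' @export
tidy.rca_hrf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a1", "b1", "a2", "b2", "w", "amplitude", "baseline"),
    estimate = c(x$a1, x$b1, x$a2, x$b2, x$w, x$amplitude, x$baseline))
}

#' @rdname tidy.rca_hrf_fit
#' @export
glance.rca_hrf_fit <- function(x, ...) {
  tibble::tibble(rise_time_s = x$rise_time_s,
                 duration_sd_s = x$duration_sd_s,
                 amplitude = x$amplitude, baseline = x$baseline,
                 rss = x$rss)
}

#' Tidy a Bland-Altman comparison
#'
#' @param x An `rca_bland_altman`.
#' @param ... Unused.
#' @return Tibble with per-pair means and differences.
#' @export
tidy.rca_bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, difference = x$differences)
}

#' @rdname tidy.rca_bland_altman
#' @export
glance.rca_bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 sd = x$sd, n = x$n)
}

#' Tidy a rigid transform
#'
#' @param x An `rca_rigid`.
#' @param ... Unused.
#' @return One-row tibble of angles (deg) and translations (mm).
#' @export
tidy.rca_rigid <- function(x, ...) {
  tibble::tibble(rx_deg = x$rotation_deg[1], ry_deg = x$rotation_deg[2],
                 rz_deg = x$rotation_deg[3],
                 tx_mm = x$translation_m[1] * 1e3,
                 ty_mm = x$translation_m[2] * 1e3,
                 tz_mm = x$translation_m[3] * 1e3)
}

#' Tidy a pulse trace
#'
#' @param x An `rca_pulse_trace`.
#' @param ... Unused.
#' @return Tibble with `time` and `value`.
#' @export
tidy.rca_pulse_trace <- function(x, ...) {
  tibble::tibble(time = x$time, value = x$values)
}
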