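#' Row-column array geometry
#'
#' Describes a row-column-addressed (RCA) 2D transducer: `n_rows` row
#' electrodes stacked along the y axis (each a strip running along x) and
#' `n_cols` column electrodes along x (strips running along y). The origin is
#' the array centre, z points into the medium. The default is a 64+64 array
#' with 150 um pitch, i.e. a 9.6 mm x 9.6 mm aperture.
#'
#' @param n_rows,n_cols Number of row / column electrodes.
#' @param pitch Element pitch in metres.
#' @param element_width Active element width in metres (<= pitch). Used for
#'   the strip-element directivity model.
#' @return An object of class `rca_array`.
#' @examples
#' arr <- array_spec()
#' aperture(arr) # 9.6 mm
#' @export
array_spec <- function(n_rows = 64L, n_cols = 64L, pitch = 150e-6,
                       element_width = pitch) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0, element_width > 0,
            element_width <= pitch + 1e-12)
  if (n_rows != n_cols) {
    stop("this RCA design requires n_rows == n_cols", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch = pitch, element_width = element_width),
    class = "rca_array"
  )
}

#' @rdname array_spec
#' @param array An `rca_array`.
#' @export
aperture <- function(array) array$n_cols * array$pitch

#' Element centre positions along one axis
#'
#' Positions of the electrode centres along their addressing axis, centred on
#' zero: rows are indexed by their y position, columns by their x position.
#'
#' @param array An `rca_array`.
#' @param axis `"rows"` or `"cols"`.
#' @return Numeric vector of positions in metres.
#' @export
element_positions <- function(array, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  n <- if (axis == "rows") array$n_rows else array$n_cols
  (seq_len(n) - (n + 1) / 2) * array$pitch
}

#' Excitation pulse description
#'
#' A Hann-windowed sinusoidal burst, optionally shaped by the transducer's
#' two-way impulse response (Gaussian spectrum of fractional -6 dB
#' bandwidth `bandwidth_frac` about `f0`). Defaults follow the
#' characterised sensor: 9.02 MHz centre frequency, two cycles, 73%
#' bandwidth, sampled at 100 MHz.
#'
#' @param f0 Centre frequency in Hz.
#' @param n_cycles Number of cycles in the burst.
#' @param fs RF sampling rate in Hz (must exceed 2 * f0).
#' @param envelope Envelope type; only `"hann"` is implemented.
#' @param bandwidth_frac Fractional two-way -6 dB bandwidth of the
#'   transducer; `NULL` disables the impulse-response shaping (the raw
#'   burst is transmitted).
#' @return An object of class `rca_pulse`.
#' @export
pulse_spec <- function(f0 = 9.02e6, n_cycles = 2L, fs = 100e6,
                       envelope = "hann", bandwidth_frac = 0.73) {
  stopifnot(f0 > 0, n_cycles >= 1, fs > 2 * f0)
  if (!is.null(bandwidth_frac)) stopifnot(bandwidth_frac > 0)
  envelope <- match.arg(envelope, "hann")
  structure(list(f0 = f0, n_cycles = n_cycles, fs = fs, envelope = envelope,
                 bandwidth_frac = bandwidth_frac),
            class = "rca_pulse")
}

#' Propagation medium
#'
#' @param c Speed of sound in m/s (default 1480, water / soft-tissue
#'   phantom).
#' @return An object of class `rca_medium`.
#' @export
medium_spec <- function(c = 1480) {
  stopifnot(c > 0)
  structure(list(c = c), class = "rca_medium")
}

#' Wavelength of a pulse in a medium
#' @param pulse An `rca_pulse`.
#' @param medium An `rca_medium`.
#' @return Wavelength in metres.
#' @export
wavelength <- function(pulse, medium) medium$c / pulse$f0

#' @export
print.rca_array <- function(x, ...) {
  cat(sprintf("<rca_array> %d rows + %d cols, pitch %.0f um, aperture %.2f mm\n",
              x$n_rows, x$n_cols, x$pitch * 1e6, aperture(x) * 1e3))
  invisible(x)
}

#' @export
print.rca_pulse <- function(x, ...) {
  cat(sprintf("<rca_pulse> %.2f MHz, %d cycles, %s envelope, fs %.0f MHz\n",
              x$f0 / 1e6, x$n_cycles, x$envelope, x$fs / 1e6))
  invisible(x)
}
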