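#' Sylvester Hadamard matrix
#'
#' Builds the order-`n` Hadamard matrix by the Sylvester recursion
#' H_2n = [[H, H], [H, -H]], so the first row and column are all +1 and
#' H %*% t(H) = n * I.
#'
#' @param order Matrix order; a power of two between 2 and 64.
#' @return An `order` x `order` matrix of +-1 with class `rca_hadamard`.
#' @examples
#' H <- hadamard_matrix(4)
#' all(H %*% t(H) == 4 * diag(4))
#' @export
hadamard_matrix <- function(order) {
  order <- as.integer(order)
  if (order < 2 || order > 64 || bitwAnd(order, order - 1L) != 0L) {
    stop("`order` must be a power of 2 between 2 and 64, got ", order,
         call. = FALSE)
  }
  H <- matrix(1, 1, 1)
  while (nrow(H) < order) {
    H <- rbind(cbind(H, H), cbind(H, -H))
  }
  structure(H, class = c("rca_hadamard", class(H)))
}

#' Linear plane-wave delay law
#'
#' Per-element firing delays for a plane wave steered at `angle_deg` in the
#' plane spanned by the element-position axis and depth. Delays are linear in
#' element position and shifted so the earliest-firing element is at t = 0.
#'
#' @param angle_deg Steering angle in degrees.
#' @param element_positions Element centre positions in metres.
#' @param c Speed of sound in m/s.
#' @return Delays in seconds, one per element.
#' @examples
#' arr <- array_spec()
#' d <- plane_wave_delays(15.5, element_positions(arr, "rows"), 1480)
#' max(d) # ~1.706 us
#' @export
plane_wave_delays <- function(angle_deg, element_positions, c) {
  stopifnot(c > 0)
  raw <- element_positions * sin(angle_deg * pi / 180) / c
  raw - min(raw)
}

new_transmit_event <- function(tx_axis, polarities, steer_angle_deg,
                               event_index) {
  structure(
    list(tx_axis = tx_axis, polarities = polarities,
         steer_angle_deg = steer_angle_deg,
         event_index = as.integer(event_index)),
    class = "rca_event"
  )
}

#' Build a transmit scheme
#'
#' Constructs one of the four RCA emission schemes:
#' \describe{
#'   \item{SA}{single-element synthetic aperture: one event per element of
#'     the transmitting array.}
#'   \item{HSA}{Hadamard-encoded synthetic aperture: all elements fire each
#'     event with +-1 polarities taken from the rows of the Sylvester
#'     Hadamard matrix.}
#'   \item{SPW}{single-array plane waves: one steered plane wave per angle,
#'     transmitted by one array.}
#'   \item{OPW}{orthogonal plane waves: the angle grid is emitted first by
#'     the rows array then by the columns array, so `n_events` is twice the
#'     per-axis angle count.}
#' }
#' For plane-wave kinds the angle grid is `seq(angle_span_deg[1],
#' angle_span_deg[2], by = angle_step_deg)`. The compound volume rate is
#' `prf_hz / n_events`.
#'
#' @param kind `"SA"`, `"HSA"`, `"SPW"` or `"OPW"`.
#' @param array An [array_spec()].
#' @param prf_hz Pulse repetition frequency in Hz.
#' @param angle_span_deg Length-2 angle interval in degrees (plane-wave kinds
#'   only).
#' @param angle_step_deg Angle step in degrees.
#' @param tx_axis Transmitting array for the single-array kinds.
#' @param max_safe_step_deg Angle step above which a grating-lobe warning is
#'   emitted (plane-wave emission grating criterion).
#' @return An object of class `rca_scheme`.
#' @examples
#' sch <- build_scheme("OPW", array_spec(), prf_hz = 20e3,
#'                     angle_span_deg = c(-15.5, 15.5), angle_step_deg = 1)
#' sch$n_events   # 64
#' frame_rate(sch) # 312.5 Hz
#' @export
build_scheme <- function(kind = c("SA", "HSA", "SPW", "OPW"), array,
                         prf_hz = 20e3,
                         angle_span_deg = c(-15.5, 15.5), angle_step_deg = 1,
                         tx_axis = "rows", max_safe_step_deg = 2) {
  kind <- match.arg(kind)
  stopifnot(inherits(array, "rca_array"), prf_hz > 0)
  n <- array$n_rows
  events <- list()
  angles <- numeric(0)

  if (kind %in% c("SPW", "OPW")) {
    span <- sort(angle_span_deg)
    n_ang <- (span[2] - span[1]) / angle_step_deg + 1
    if (abs(n_ang - round(n_ang)) > 1e-9) {
      stop("angle span is not an integer multiple of the angle step",
           call. = FALSE)
    }
    angles <- seq(span[1], span[2], by = angle_step_deg)
    if (angle_step_deg > max_safe_step_deg) {
      warning("angle step ", angle_step_deg,
              " deg exceeds the grating-lobe-safe maximum of ",
              max_safe_step_deg, " deg", call. = FALSE)
    }
  }

  idx <- 0L
  if (kind == "SA") {
    for (e in seq_len(n)) {
      pol <- numeric(n); pol[e] <- 1
      idx <- idx + 1L
      events[[idx]] <- new_transmit_event(tx_axis, pol, 0, idx)
    }
  } else if (kind == "HSA") {
    H <- hadamard_matrix(n)
    for (e in seq_len(n)) {
      idx <- idx + 1L
      events[[idx]] <- new_transmit_event(tx_axis, H[e, ], 0, idx)
    }
  } else if (kind == "SPW") {
    for (a in angles) {
      idx <- idx + 1L
      events[[idx]] <- new_transmit_event(tx_axis, rep(1, n), a, idx)
    }
  } else { # OPW: all rows-axis angles ascending, then all cols-axis angles
    for (ax in c("rows", "cols")) {
      for (a in angles) {
        idx <- idx + 1L
        events[[idx]] <- new_transmit_event(ax, rep(1, n), a, idx)
      }
    }
  }

  structure(
    list(name = kind, events = events, prf_hz = prf_hz,
         n_events = length(events), angles_deg = angles, array = array),
    class = "rca_scheme"
  )
}

#' Compound volume rate of a scheme
#'
#' One compounded volume needs all `n_events` transmits, so the volume rate
#' is `prf_hz / n_events`; e.g. 64 orthogonal plane waves at a 20 kHz PRF
#' give 312.5 volumes per second.
#'
#' @param scheme An `rca_scheme`.
#' @return Frame rate in Hz.
#' @export
frame_rate <- function(scheme) {
  stopifnot(inherits(scheme, "rca_scheme"), scheme$n_events >= 1)
  scheme$prf_hz / scheme$n_events
}

#' Receive axis of an event
#'
#' The array orthogonal to the transmitting one receives: rows transmit,
#' columns receive, and vice versa.
#' @param event An `rca_event`.
#' @return `"rows"` or `"cols"`.
#' @export
rx_axis <- function(event) if (event$tx_axis == "rows") "cols" else "rows"

#' Decode Hadamard-encoded channel data
#'
#' Inverts Hadamard encoding: decoded event k is `(1/order) * sum_m H[m, k] *
#' encoded[m]`, an exact left inverse of the encoding in the linear model, so
#' noiseless HSA data decode to the single-element synthetic-aperture data
#' while iid channel noise variance is divided by `order`.
#'
#' @param encoded An `rca_channel_data` acquired with an HSA scheme.
#' @param H The Hadamard matrix used for encoding (defaults to the Sylvester
#'   matrix of the event count).
#' @return An `rca_channel_data` with single-element equivalent events.
#' @export
hadamard_decode <- function(encoded, H = NULL) {
  stopifnot(inherits(encoded, "rca_channel_data"))
  d <- dim(encoded$samples) # [time, rx, event, frame]
  n_ev <- d[3]
  if (is.null(H)) H <- hadamard_matrix(n_ev)
  if (nrow(H) != n_ev) {
    stop("event count (", n_ev, ") does not match Hadamard order (",
         nrow(H), ")", call. = FALSE)
  }
  x <- encoded$samples
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  out <- x
  for (f in seq_len(d[4])) {
    out[, , f] <- x[, , f] %*% H / n_ev
  }
  dim(out) <- d
  res <- encoded
  res$samples <- out
  # decoded data behave like an SA acquisition of the same geometry
  if (!is.null(res$scheme) && res$scheme$name == "HSA") {
    sa <- res$scheme
    sa$name <- "SA"
    n <- sa$array$n_rows
    for (e in seq_len(sa$n_events)) {
      pol <- numeric(n); pol[e] <- 1
      sa$events[[e]]$polarities <- pol
    }
    res$scheme <- sa
  }
  res$decoded <- TRUE
  res
}

#' Hadamard-encode single-element channel data
#'
#' Forms the encoded event stack `encoded[m] = sum_k H[m, k] * sa[k]`. In the
#' linear propagation model this equals firing all elements simultaneously
#' with the +-1 polarities of row m, so it doubles as the fast simulation
#' path for HSA ensembles.
#'
#' @param sa_data An `rca_channel_data` from an SA acquisition.
#' @param H Hadamard matrix (defaults to the Sylvester matrix of the event
#'   count).
#' @return Encoded `rca_channel_data`.
#' @export
hadamard_encode <- function(sa_data, H = NULL) {
  stopifnot(inherits(sa_data, "rca_channel_data"))
  d <- dim(sa_data$samples)
  n_ev <- d[3]
  if (is.null(H)) H <- hadamard_matrix(n_ev)
  stopifnot(nrow(H) == n_ev)
  x <- sa_data$samples
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  out <- x
  for (f in seq_len(d[4])) {
    out[, , f] <- x[, , f] %*% t(H)
  }
  dim(out) <- d
  res <- sa_data
  res$samples <- out
  if (!is.null(res$scheme) && res$scheme$name == "SA") {
    hs <- res$scheme
    hs$name <- "HSA"
    for (e in seq_len(hs$n_events)) {
      hs$events[[e]]$polarities <- H[e, ]
    }
    res$scheme <- hs
  }
  res
}

#' Serialize / restore a scheme as a plain list
#'
#' Round-trips the scheme through the fields a run configuration stores
#' (kind, PRF, angle span and step, transmit axis).
#' @param scheme An `rca_scheme`.
#' @return A named list suitable for YAML/JSON.
#' @export
scheme_to_config <- function(scheme) {
  list(kind = scheme$name, prf_hz = scheme$prf_hz,
       angle_span_deg = if (length(scheme$angles_deg)) range(scheme$angles_deg) else NULL,
       angle_step_deg = if (length(scheme$angles_deg) > 1) diff(scheme$angles_deg[1:2]) else NULL,
       tx_axis = scheme$events[[1]]$tx_axis,
       n_events = scheme$n_events)
}

#' @rdname scheme_to_config
#' @param config A list produced by [scheme_to_config()].
#' @param array An [array_spec()].
#' @export
scheme_from_config <- function(config, array) {
  build_scheme(config$kind, array, prf_hz = config$prf_hz,
               angle_span_deg = if (is.null(config$angle_span_deg)) c(-15.5, 15.5) else config$angle_span_deg,
               angle_step_deg = if (is.null(config$angle_step_deg)) 1 else config$angle_step_deg,
               tx_axis = if (is.null(config$tx_axis)) "rows" else config$tx_axis)
}

#' Standard scheme presets
#'
#' Named presets matching the sequence table of the phantom study: SA64,
#' HSA64, OPW32+32, OPW16+16, OPW8+8, SPW64, SPW32, SPW16, all at a 20 kHz
#' PRF by default.
#'
#' @param name Preset name, e.g. `"OPW32+32"`.
#' @param array An [array_spec()].
#' @param prf_hz Pulse repetition frequency.
#' @return An `rca_scheme`.
#' @export
scheme_preset <- function(name, array = array_spec(), prf_hz = 20e3) {
  spans <- list(
    "SA64"     = list("SA", NULL),
    "HSA64"    = list("HSA", NULL),
    "OPW32+32" = list("OPW", c(-15.5, 15.5)),
    "OPW16+16" = list("OPW", c(-7.5, 7.5)),
    "OPW8+8"   = list("OPW", c(-3.5, 3.5)),
    "SPW64"    = list("SPW", c(-31.5, 31.5)),
    "SPW32"    = list("SPW", c(-15.5, 15.5)),
    "SPW16"    = list("SPW", c(-7.5, 7.5))
  )
  if (!name %in% names(spans)) {
    stop("unknown preset: ", name, call. = FALSE)
  }
  p <- spans[[name]]
  if (is.null(p[[2]])) {
    build_scheme(p[[1]], array, prf_hz = prf_hz)
  } else {
    build_scheme(p[[1]], array, prf_hz = prf_hz, angle_span_deg = p[[2]],
                 angle_step_deg = 1)
  }
}

#' @export
print.rca_scheme <- function(x, ...) {
  cat(sprintf("<rca_scheme> %s: %d events, PRF %.3g kHz, frame rate %.4g Hz\n",
              x$name, x$n_events, x$prf_hz / 1e3, frame_rate(x)))
  invisible(x)
}
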