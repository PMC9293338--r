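# Contrast-specific three-pulse imaging, time-intensity curves and the
# triangular indicator-dilution model.

#' Three-pulse contrast imaging scheme
#'
#' The combined pulse-inversion/amplitude-modulation scheme: one
#' high-amplitude pulse followed by two pulses at half the amplitude and
#' opposite phase, encoded as relative transmit amplitudes `[1, -0.5, -0.5]`.
#' Summing the three responses cancels any component linear in transmit
#' amplitude and retains the nonlinear contrast signal.
#'
#' @param amplitudes relative transmit amplitudes of the three pulses; must
#'   sum to zero with the second and third at half the magnitude of the
#'   first.
#' @param f0 transmit frequency (MHz).
#' @param n_cycles cycles per imaging pulse.
#' @param mi mechanical index of the high-amplitude pulse.
#' @return A `pulse_scheme` list.
#' @export
pulse_scheme <- function(amplitudes = c(1, -0.5, -0.5), f0 = 3.5,
                         n_cycles = 3L, mi = 0.2) {
  if (length(amplitudes) != 3) {
    stop("the contrast scheme uses exactly three pulses", call. = FALSE)
  }
  if (abs(sum(amplitudes)) > 1e-12) {
    stop("scheme amplitudes must sum to zero (linear cancellation)",
         call. = FALSE)
  }
  if (abs(abs(amplitudes[2]) - abs(amplitudes[1]) / 2) > 1e-12 ||
      abs(abs(amplitudes[3]) - abs(amplitudes[1]) / 2) > 1e-12) {
    stop("pulses 2 and 3 must have half the magnitude of pulse 1",
         call. = FALSE)
  }
  check_scalar(f0, "f0", positive = TRUE)
  check_scalar(mi, "mi", positive = TRUE)
  structure(list(amplitudes = amplitudes, f0 = f0,
                 n_cycles = as.integer(n_cycles), mi = mi),
            class = "pulse_scheme")
}

#' Combine the three pulse responses into the nonlinear frame
#'
#' Sums the RF-like signed responses to the three transmit pulses and takes
#' the envelope (modulus) of the sum. Any scatterer whose response is linear
#' in transmit amplitude cancels exactly under the `[1, -0.5, -0.5]` scheme;
#' the residual is the nonlinear contrast signal.
#'
#' @param p1,p2,p3 per-pulse responses (vectors, matrices or arrays of equal
#'   shape), signed, before envelope detection.
#' @param envelope take the modulus of the sum (default); set `FALSE` for
#'   the signed RF-domain sum.
#' @return The combined nonlinear response, same shape as the inputs.
#' @export
combine_pulses <- function(p1, p2, p3, envelope = TRUE) {
  if (!identical(dim(p1) %||% length(p1), dim(p2) %||% length(p2)) ||
      !identical(dim(p1) %||% length(p1), dim(p3) %||% length(p3))) {
    stop("pulse responses must have identical shapes", call. = FALSE)
  }
  s <- p1 + p2 + p3
  if (envelope) abs(s) else s
}

#' Combined nonlinear frames of a simulated clip
#'
#' @param clip a `dceus_clip` from [simulate_dceus_clip()].
#' @return Array `ny x nx x nt` of combined nonlinear envelope frames.
#' @export
combine_clip <- function(clip) {
  stopifnot(inherits(clip, "dceus_clip"))
  combine_pulses(clip$p1, clip$p2, clip$p3)
}

#' Maximum intensity projection of a frame sequence
#'
#' Per-pixel maximum over time, visualizing every perfused region of the
#' clip.
#'
#' @param frames `ny x nx x nt` array or list of equal-sized matrices.
#' @return A `ny x nx` matrix.
#' @export
max_intensity_projection <- function(frames) {
  if (is.list(frames)) {
    if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
    frames <- simplify2array(frames)
  }
  if (length(dim(frames)) == 2) return(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] < 1) {
    stop("empty frame sequence", call. = FALSE)
  }
  apply(frames, c(1, 2), max)
}

#' Extract a time-intensity curve from combined nonlinear frames
#'
#' ROI mean of the linearized pixel values per frame. Gray levels represent
#' signal envelopes (no log compression), so linearization squares them:
#' intensity is proportional to backscattered energy.
#'
#' @param frames combined nonlinear envelope frames (`ny x nx x nt` array or
#'   list of matrices), or a `dceus_clip` (combined internally).
#' @param roi rectangle `c(x0, y0, x1, y1)`, 0-based, half-open; `NULL` for
#'   the whole image.
#' @param times frame times (s), strictly increasing; taken from the clip
#'   when a `dceus_clip` is given.
#' @return A `tic`: `t`, `intensity`, `peak_value`, `peak_time`.
#' @export
extract_tic <- function(frames, roi = NULL, times = NULL) {
  if (inherits(frames, "dceus_clip")) {
    times <- times %||% frames$times
    frames <- combine_clip(frames)
  }
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3) stop("need a frame sequence", call. = FALSE)
  nt <- dim(frames)[3]
  times <- times %||% seq_len(nt)
  if (length(times) != nt || any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing, one per frame",
         call. = FALSE)
  }
  idx <- roi_indices(dim(frames)[1:2], roi)
  intensity <- vapply(seq_len(nt), function(i) {
    mean(frames[idx$rows, idx$cols, i]^2)
  }, numeric(1))
  new_tic(times, intensity)
}

new_tic <- function(t, intensity) {
  ipk <- which.max(intensity)
  structure(list(t = t, intensity = intensity,
                 peak_value = intensity[ipk], peak_time = t[ipk]),
            class = "tic")
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("TIC: %d frames over %.1f s; peak %.4g at t = %.2f s\n",
              length(x$t), max(x$t) - min(x$t), x$peak_value, x$peak_time))
  invisible(x)
}

#' @export
plot.tic <- function(x, ...) {
  graphics::plot(x$t, x$intensity, type = "l", xlab = "Time (s)",
                 ylab = "Linearized intensity", ...)
  graphics::points(x$peak_time, x$peak_value, pch = 19)
  invisible(x)
}

#' Moving-average smoothing of a time-intensity curve
#'
#' Optional centered moving average suppressing the periodic fluctuation of
#' pulsatile flow; the window should span one pulsation period.
#'
#' @param tic a `tic`.
#' @param window_s smoothing window length (s).
#' @return A smoothed `tic` (peak fields recomputed).
#' @export
smooth_tic <- function(tic, window_s) {
  stopifnot(inherits(tic, "tic"))
  check_scalar(window_s, "window_s", positive = TRUE)
  dt <- stats::median(diff(tic$t))
  k <- max(1L, round(window_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  n <- length(tic$intensity)
  sm <- vapply(seq_len(n), function(i) {
    mean(tic$intensity[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  new_tic(tic$t, sm)
}

#' Percent difference between two TIC peaks
#'
#' `100 * (peak_a - peak_b) / peak_b`; positive when curve `a` peaks higher
#' (the reporting convention "a% greater"), negative when lower.
#'
#' @param tic_a,tic_b `tic` objects (or lists with a `peak_value` field);
#'   both peaks must be positive.
#' @return Percent difference.
#' @export
peak_percent_difference <- function(tic_a, tic_b) {
  pa <- tic_a$peak_value
  pb <- tic_b$peak_value
  if (is.null(pa) || is.null(pb) || pa <= 0 || pb <= 0) {
    stop("both TIC peaks must be positive", call. = FALSE)
  }
  100 * (pa - pb) / pb
}

#' Peak concentration and mixing volume of a triangular bolus
#'
#' Under the triangular indicator-dilution model only mass conservation and
#' the base duration constrain the transit, giving
#' `C_peak = 2 * dose / (Q * T_b)` (flow converted to mL/s) and mixing
#' volume `V_mix = dose / C_peak`.
#'
#' @param dose injected quantity (mg).
#' @param flow volumetric flow (mL/min).
#' @param duration triangle base duration (s).
#' @return A list: `c_peak` (mg/mL) and `v_mix` (mL).
#' @export
triangular_peak_concentration <- function(dose, flow, duration) {
  check_scalar(dose, "dose", positive = TRUE)
  check_scalar(flow, "flow", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  q_s <- flow / 60
  c_peak <- 2 * dose / (q_s * duration)
  list(c_peak = c_peak, v_mix = dose / c_peak)
}

#' Normalize a set of TICs to their maximum peak
#'
#' Divides every curve by the maximum peak across the set, so the largest
#' resulting peak is exactly 1 (the convention used when comparing agents on
#' one plot).
#'
#' @param tics list of `tic` objects; the maximum peak must be positive.
#' @return List of normalized `tic` objects, in input order.
#' @export
normalize_tics <- function(tics) {
  if (length(tics) < 1) stop("need at least one TIC", call. = FALSE)
  peaks <- vapply(tics, function(x) x$peak_value, numeric(1))
  mx <- max(peaks)
  if (mx <= 0) stop("all TICs are zero", call. = FALSE)
  lapply(tics, function(x) new_tic(x$t, x$intensity / mx))
}
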