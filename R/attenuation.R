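# Insertion-loss attenuation estimation, linear backscatter fraction and the
# accompanying sanity checks.

#' Cuvette geometry for attenuation estimation
#'
#' @param d one-way path length through the agent medium (cm).
#' @param transmit_coefficient transmit coefficient T of the container walls;
#'   approximated to 1 in the characterization study (reflection losses
#'   neglected).
#' @param path_factor 1 for through-transmission, 2 for echo mode (forward
#'   and backward passage through the dispersion).
#' @return A `cuvette_geometry` list.
#' @export
cuvette_geometry <- function(d = 1, transmit_coefficient = 1,
                             path_factor = 1) {
  check_scalar(d, "d", positive = TRUE)
  check_scalar(transmit_coefficient, "transmit_coefficient")
  if (transmit_coefficient <= 0 || transmit_coefficient > 1) {
    stop("transmit coefficient must be in (0, 1]", call. = FALSE)
  }
  if (!path_factor %in% c(1, 2)) {
    stop("path_factor must be 1 (transmission) or 2 (echo mode)",
         call. = FALSE)
  }
  structure(list(d = d, transmit_coefficient = transmit_coefficient,
                 path_factor = path_factor), class = "cuvette_geometry")
}

#' Attenuation coefficient from a through-transmission amplitude pair
#'
#' Insertion-loss estimate
#' `alpha = (20 / (path_factor * d)) * log10(T * a_sal / a_ca)` in dB/cm,
#' from the fundamental amplitude transmitted through the reference (saline)
#' and through the agent dispersion. With `path_factor = 1` this is the
#' through-transmission form; antisymmetric under swapping the amplitudes at
#' `T = 1`.
#'
#' @param a_sal fundamental amplitude through saline (linear units, > 0).
#' @param a_ca fundamental amplitude through the agent dispersion (> 0).
#' @param geom a [cuvette_geometry()].
#' @return Attenuation coefficient in dB/cm.
#' @export
attenuation_through_transmission <- function(a_sal, a_ca,
                                             geom = cuvette_geometry()) {
  stopifnot(inherits(geom, "cuvette_geometry"))
  if (any(a_sal <= 0) || any(a_ca <= 0)) {
    stop("amplitudes must be positive", call. = FALSE)
  }
  (20 / (geom$path_factor * geom$d)) *
    log10(geom$transmit_coefficient * a_sal / a_ca)
}

#' Attenuation coefficient from echo-mode reflector gray levels
#'
#' Echo-mode variant of the insertion-loss estimate: the mean gray level of a
#' reflector plate imaged through saline versus through the agent dispersion,
#' with the effective path doubled (forward and backward passage), i.e.
#' [attenuation_through_transmission()] with `path_factor = 2`.
#'
#' @param gray_sal mean reflector gray level with saline in the cuvette (> 0).
#' @param gray_ca mean reflector gray level with agent in the cuvette (> 0).
#' @param geom a [cuvette_geometry()]; the path factor is forced to 2.
#' @return Attenuation coefficient in dB/cm.
#' @export
attenuation_echo_mode <- function(gray_sal, gray_ca,
                                  geom = cuvette_geometry(path_factor = 2)) {
  stopifnot(inherits(geom, "cuvette_geometry"))
  if (any(gray_sal <= 0) || any(gray_ca <= 0)) {
    stop("gray levels must be positive", call. = FALSE)
  }
  geom$path_factor <- 2
  attenuation_through_transmission(gray_sal, gray_ca, geom)
}

#' Mean reflector gray level over frames and ROI
#'
#' @param frames envelope image stack: a `ny x nx x nframes` array or a list
#'   of equal-sized matrices.
#' @param roi rectangle `c(x0, y0, x1, y1)` in pixel coordinates, 0-based,
#'   half-open; `NULL` for the whole image.
#' @return Mean gray level over the ROI and all frames.
#' @export
mean_reflector_level <- function(frames, roi = NULL) {
  if (is.list(frames)) {
    if (length(frames) == 0) stop("need at least one frame", call. = FALSE)
    frames <- simplify2array(frames)
  }
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  if (length(dim(frames)) != 3 || dim(frames)[3] < 1) {
    stop("need at least one frame", call. = FALSE)
  }
  idx <- roi_indices(dim(frames)[1:2], roi)
  mean(frames[idx$rows, idx$cols, , drop = FALSE])
}

#' Linear backscatter fraction
#'
#' Ratio of the backscattered amplitude to the transmitted amplitude,
#' `S_lin = 100 * A_backsc / A_transmit` (percent). At the low pressures of
#' the attenuation protocol higher-harmonic generation is negligible, so the
#' fraction quantifies linear scatter at the fundamental.
#'
#' @param a_backsc mean backscatter amplitude inside the dispersion (>= 0).
#' @param a_transmit transmitted (sonicating) amplitude (> 0), typically from
#'   [reflection_corrected_transmit()].
#' @return Percentage.
#' @export
linear_backscatter_fraction <- function(a_backsc, a_transmit) {
  if (any(a_transmit <= 0)) stop("transmit amplitude must be positive",
                                 call. = FALSE)
  if (any(a_backsc < 0)) stop("backscatter amplitude must be nonnegative",
                              call. = FALSE)
  100 * a_backsc / a_transmit
}

#' Pressure reflection coefficient from acoustic impedances
#'
#' `r = (Z2 - Z1) / (Z2 + Z1)` at normal incidence. Defaults are water
#' (1.48 MRayl) against aluminum (17.3 MRayl), the reflector interface of the
#' echo-mode protocol.
#'
#' @param z1,z2 acoustic impedances (MRayl), both positive.
#' @return Reflection coefficient in (0, 1).
#' @export
reflection_coefficient <- function(z1 = 1.48, z2 = 17.3) {
  check_scalar(z1, "z1", positive = TRUE)
  check_scalar(z2, "z2", positive = TRUE)
  (z2 - z1) / (z2 + z1)
}

#' Sonicating amplitude from the reflector gray level
#'
#' The reflector gray level divided by the reflection coefficient of the
#' water-reflector interface recovers the sonicating (transmit) amplitude.
#'
#' @param gray_plate mean reflector gray level with no cuvette in the path.
#' @param r_interface reflection coefficient, in (0, 1].
#' @return Sonicating amplitude (same units as the gray level).
#' @export
reflection_corrected_transmit <- function(gray_plate,
                                          r_interface =
                                            reflection_coefficient()) {
  check_scalar(r_interface, "r_interface")
  if (r_interface <= 0 || r_interface > 1) {
    stop("reflection coefficient must be in (0, 1]", call. = FALSE)
  }
  gray_plate / r_interface
}

#' Speed-of-sound difference implied by an arrival delay
#'
#' Converts the arrival delay of a pulse transmitted through the agent
#' dispersion (relative to the reference medium) into the relative
#' speed-of-sound difference over the path:
#' `100 * (c_ref - d / (d/c_ref + delay)) / c_ref` percent.
#'
#' @param delay_us arrival delay (microseconds); positive when the pulse
#'   through the agent arrives later.
#' @param d_cm path length (cm).
#' @param c_ref reference speed of sound (m/s), water by default.
#' @return Speed-of-sound difference in percent of `c_ref`.
#' @export
sound_speed_difference <- function(delay_us, d_cm = 1, c_ref = 1480) {
  check_scalar(d_cm, "d_cm", positive = TRUE)
  check_scalar(c_ref, "c_ref", positive = TRUE)
  d_m <- d_cm / 100
  t_total_s <- d_m / c_ref + delay_us * 1e-6
  if (any(t_total_s <= 0)) {
    stop("nonphysical: total travel time must be positive", call. = FALSE)
  }
  c_medium <- d_m / t_total_s
  100 * (c_ref - c_medium) / c_ref
}

#' Fundamental amplitude of an acquisition
#'
#' Segments the record, computes its averaged amplitude spectrum and returns
#' the amplitude at the transmit frequency, the quantity entering the
#' insertion-loss estimate.
#'
#' @inheritParams segment_pulses
#' @param window taper passed to [averaged_amplitude_spectrum()].
#' @param method amplitude estimator passed to [extract_harmonics()].
#' @return Fundamental amplitude (linear units).
#' @export
fundamental_amplitude <- function(rec, window_us = 9, window = "hanning",
                                  method = "interp") {
  spec <- averaged_amplitude_spectrum(segment_pulses(rec, window_us), window)
  extract_harmonics(spec, orders = 1, method = method)$amplitude
}

#' Estimate attenuation from a reference/agent record pair
#'
#' Full through-transmission pipeline: per-pulse segmentation, averaged
#' amplitude spectra, fundamental amplitudes for the reference and agent
#' records, and the insertion-loss estimate of
#' [attenuation_through_transmission()]. When `qc = TRUE` the agent record's
#' second-harmonic/fundamental ratio is checked against the linear-regime
#' criterion (below 5%) and a warning is raised otherwise.
#'
#' @param ref reference (saline) `acquisition_record`.
#' @param agent agent `acquisition_record`.
#' @param geom a [cuvette_geometry()].
#' @param window_us analysis window length (microseconds).
#' @param qc run the linear-regime QC check on the agent record.
#' @return A list: `alpha` (dB/cm), `f` (MHz), `a_ref`, `a_agent`, `geom`.
#' @export
estimate_attenuation <- function(ref, agent, geom = cuvette_geometry(),
                                 window_us = 9, qc = TRUE) {
  stopifnot(inherits(ref, "acquisition_record"),
            inherits(agent, "acquisition_record"))
  spec_ref <- averaged_amplitude_spectrum(segment_pulses(ref, window_us))
  spec_ca <- averaged_amplitude_spectrum(segment_pulses(agent, window_us))
  a_ref <- extract_harmonics(spec_ref, orders = 1)$amplitude
  if (qc && 2 * agent$f0 < agent$fs / 2) {
    h <- extract_harmonics(spec_ca, orders = c(1, 2))
    ratio <- h$amplitude[h$order == 2] / h$amplitude[h$order == 1]
    a_ca <- h$amplitude[h$order == 1]
    if (is.finite(ratio) && ratio > 0.05) {
      warning(sprintf(
        "second harmonic is %.1f%% of the fundamental (> 5%%): %s",
        100 * ratio, "attenuation assumes the linear oscillation regime"),
        call. = FALSE)
    }
  } else {
    a_ca <- extract_harmonics(spec_ca, orders = 1)$amplitude
  }
  list(alpha = attenuation_through_transmission(a_ref, a_ca, geom),
       f = agent$f0, a_ref = a_ref, a_agent = a_ca, geom = geom)
}

#' Aggregate attenuation estimates over replicate pairs
#'
#' Applies [estimate_attenuation()] to each reference/agent pair and reports
#' the replicate mean and sample standard deviation, mirroring the
#' 15-acquisition protocol.
#'
#' @param pairs list of pairs, each a list with elements `reference` and
#'   `agent` (as returned by [simulate_transmission_pair()]).
#' @inheritParams estimate_attenuation
#' @return An `attenuation_result`: `f`, `alpha_mean`, `alpha_sd`, `n`,
#'   `values`.
#' @export
attenuation_replicates <- function(pairs, geom = cuvette_geometry(),
                                   window_us = 9, qc = FALSE) {
  if (length(pairs) < 1) stop("need at least one pair", call. = FALSE)
  vals <- vapply(pairs, function(p) {
    estimate_attenuation(p$reference, p$agent, geom, window_us, qc)$alpha
  }, numeric(1))
  structure(list(
    f = pairs[[1]]$agent$f0,
    alpha_mean = mean(vals),
    alpha_sd = if (length(vals) > 1) stats::sd(vals) else 0,
    n = length(vals),
    values = vals
  ), class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf("Attenuation at %g MHz: %.3f +/- %.3f dB/cm (n = %d)\n",
              x$f, x$alpha_mean, x$alpha_sd, x$n))
  invisible(x)
}
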