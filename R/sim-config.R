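#' Configuration of a synthetic tone-burst acquisition
#'
#' Holds the acquisition-protocol constants and ground truth used by the
#' synthetic generators: transmit frequency and burst length, sampling rate,
#' number of pulses per acquisition and inter-pulse silence, the prescribed
#' harmonic content of the scattered signal, the attenuation of the simulated
#' propagation path, the replicate structure and the RNG seed.
#'
#' The generators prescribe harmonic content directly (no bubble-dynamics
#' model): each pulse is a windowed tone burst with components at `k * f0`
#' whose linear amplitudes relative to the fundamental are given by
#' `harmonic_ratios`, plus an optional subharmonic at `f0 / 2`.
#'
#' @param f0 transmit frequency (MHz).
#' @param n_cycles integer number of cycles per tone burst. The in-vitro
#'   protocol used 10 cycles at 1.0 MHz and 20 cycles at 2.25 and 3.5 MHz.
#' @param fs sampling rate (MHz).
#' @param n_pulses pulses per acquisition; the protocol transmitted 92-95.
#' @param silence_us inter-pulse silence (microseconds).
#' @param harmonic_ratios named numeric vector mapping integer harmonic order
#'   (as name) to linear amplitude relative to the fundamental; must contain
#'   order 1 with value 1.
#' @param subharmonic_ratio linear amplitude at `f0 / 2` relative to the
#'   fundamental.
#' @param noise_rms RMS amplitude of the additive white Gaussian noise floor.
#' @param alpha_true attenuation coefficient (dB/cm) of the simulated medium,
#'   used by [simulate_transmission_pair()].
#' @param d one-way path length in the medium (cm).
#' @param n_replicates number of replicate acquisitions per agent.
#' @param replicate_cv coefficient of variation of per-harmonic amplitudes
#'   across replicates (lognormal multiplicative scatter).
#' @param seed integer RNG seed; fixes all generator output bit-for-bit.
#' @param envelope tone-burst envelope, `"rectangular"` (side-scatter and
#'   through-transmission protocol) or `"gaussian"` (echo-mode protocol).
#' @param random_phases draw a random phase per spectral component instead of
#'   the default zero phase (amplitude spectra are unaffected).
#' @param travel_time_us acoustic travel time from pulse emission to the
#'   arrival of the scattered signal, stored in record metadata and used as
#'   the default segmentation offset.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_scatter_acquisition()], [simulate_transmission_pair()],
#'   [simulate_dceus_clip()]
#' @export
sim_config <- function(f0 = 1.0, n_cycles = 10L, fs = 25, n_pulses = 93L,
                       silence_us = 250, harmonic_ratios = c("1" = 1),
                       subharmonic_ratio = 0, noise_rms = 0,
                       alpha_true = 0, d = 1, n_replicates = 15L,
                       replicate_cv = 0.1, seed = 1L,
                       envelope = c("rectangular", "gaussian"),
                       random_phases = FALSE, travel_time_us = 0) {
  envelope <- match.arg(envelope)
  check_scalar(f0, "f0", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(n_cycles, "n_cycles", positive = TRUE)
  check_scalar(silence_us, "silence_us", positive = TRUE)
  check_scalar(noise_rms, "noise_rms", nonnegative = TRUE)
  check_scalar(alpha_true, "alpha_true", nonnegative = TRUE)
  check_scalar(d, "d", positive = TRUE)
  check_scalar(subharmonic_ratio, "subharmonic_ratio", nonnegative = TRUE)
  check_scalar(replicate_cv, "replicate_cv", nonnegative = TRUE)
  check_scalar(travel_time_us, "travel_time_us", nonnegative = TRUE)
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 92L || n_pulses > 95L) {
    stop("n_pulses must be in 92..95 (acquisition protocol)", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)

  orders <- suppressWarnings(as.numeric(names(harmonic_ratios)))
  if (is.null(names(harmonic_ratios)) || anyNA(orders)) {
    stop("harmonic_ratios must be a named numeric vector with numeric orders",
         call. = FALSE)
  }
  if (any(orders < 1) || any(orders != round(orders))) {
    stop("harmonic orders must be integers >= 1 (use subharmonic_ratio for f0/2)",
         call. = FALSE)
  }
  if (!("1" %in% names(harmonic_ratios)) ||
      harmonic_ratios[["1"]] != 1) {
    stop("harmonic_ratios must contain order 1 with value 1", call. = FALSE)
  }
  if (any(harmonic_ratios < 0)) {
    stop("harmonic ratios must be nonnegative", call. = FALSE)
  }
  f_max <- max(orders) * f0
  if (fs <= 2 * f_max) {
    stop(sprintf(
      "aliasing: fs = %g MHz must exceed twice the highest harmonic (%g MHz)",
      fs, f_max), call. = FALSE)
  }

  structure(list(
    f0 = f0, n_cycles = n_cycles, fs = fs, n_pulses = n_pulses,
    silence_us = silence_us, harmonic_ratios = harmonic_ratios,
    subharmonic_ratio = subharmonic_ratio, noise_rms = noise_rms,
    alpha_true = alpha_true, d = d, n_replicates = n_replicates,
    replicate_cv = replicate_cv, seed = as.integer(seed),
    envelope = envelope, random_phases = random_phases,
    travel_time_us = travel_time_us
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic acquisition configuration\n")
  cat(sprintf("  f0 %g MHz, %d cycles (%s envelope), fs %g MHz\n",
              x$f0, x$n_cycles, x$envelope, x$fs))
  cat(sprintf("  %d pulses, %g us silence, %d replicates (CV %g)\n",
              x$n_pulses, x$silence_us, x$n_replicates, x$replicate_cv))
  ords <- paste(sprintf("%s:%g", names(x$harmonic_ratios), x$harmonic_ratios),
                collapse = ", ")
  cat(sprintf("  harmonic ratios {%s}, subharmonic %g\n",
              ords, x$subharmonic_ratio))
  cat(sprintf("  noise RMS %g, alpha_true %g dB/cm over d = %g cm, seed %d\n",
              x$noise_rms, x$alpha_true, x$d, x$seed))
  invisible(x)
}

#' Duration of the simulated tone burst
#'
#' @param cfg a [sim_config()].
#' @return Burst duration in microseconds (`n_cycles / f0`).
#' @export
burst_duration_us <- function(cfg) cfg$n_cycles / cfg$f0

#' Configuration of a simulated contrast bolus
#'
#' Parameters of the bolus wash-in/wash-out imaged by the dynamic
#' contrast-enhanced (DCE-US) generator: injected dose, carrier flow, the
#' triangular transit, the pulsatile-flow modulation attributed to a
#' peristaltic pump, and the recording geometry.
#'
#' @param dose injected agent quantity (mg).
#' @param flow volumetric carrier flow (mL/min).
#' @param transit_duration base duration of the triangular concentration
#'   transit at the measurement site (s).
#' @param arrival_time bolus arrival time at the site (s).
#' @param pulsatility_amp relative amplitude of the periodic flow fluctuation.
#' @param pulsatility_freq frequency of the flow fluctuation (Hz).
#' @param frame_rate imaging frame rate (frames/s).
#' @param clip_duration recorded clip duration (s); must cover arrival plus
#'   transit.
#'
#' @return An object of class `bolus_config`.
#' @export
bolus_config <- function(dose = 0.5, flow = 36, transit_duration = 20,
                         arrival_time = 5, pulsatility_amp = 0.1,
                         pulsatility_freq = 1, frame_rate = 10,
                         clip_duration = 40) {
  check_scalar(dose, "dose", nonnegative = TRUE)
  check_scalar(flow, "flow", positive = TRUE)
  check_scalar(transit_duration, "transit_duration", positive = TRUE)
  check_scalar(arrival_time, "arrival_time", nonnegative = TRUE)
  check_scalar(pulsatility_amp, "pulsatility_amp", nonnegative = TRUE)
  check_scalar(pulsatility_freq, "pulsatility_freq", nonnegative = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  check_scalar(clip_duration, "clip_duration", positive = TRUE)
  if (clip_duration < arrival_time + transit_duration) {
    stop("clip_duration must cover arrival_time + transit_duration",
         call. = FALSE)
  }
  structure(list(
    dose = dose, flow = flow, transit_duration = transit_duration,
    arrival_time = arrival_time, pulsatility_amp = pulsatility_amp,
    pulsatility_freq = pulsatility_freq, frame_rate = frame_rate,
    clip_duration = clip_duration
  ), class = "bolus_config")
}

#' @export
print.bolus_config <- function(x, ...) {
  cat(sprintf(
    "Bolus: %g mg at %g mL/min; arrival %g s, transit %g s, clip %g s @ %g fps\n",
    x$dose, x$flow, x$arrival_time, x$transit_duration, x$clip_duration,
    x$frame_rate))
  if (x$pulsatility_amp > 0) {
    cat(sprintf("  pulsatile modulation: %g%% at %g Hz\n",
                100 * x$pulsatility_amp, x$pulsatility_freq))
  }
  invisible(x)
}
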