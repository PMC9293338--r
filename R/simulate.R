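# Synthetic acquisition generators. Harmonic content is prescribed, not
# emergent: no bubble-dynamics ODE and no diffraction modelling.

# One windowed tone burst. `amps` is a two-column matrix: order, amplitude.
make_burst <- function(cfg, amps, phases = NULL) {
  nb <- round(burst_duration_us(cfg) * cfg$fs)
  t_us <- (seq_len(nb) - 1) / cfg$fs
  env <- switch(cfg$envelope,
    rectangular = rep(1, nb),
    gaussian = {
      tc <- (nb - 1) / (2 * cfg$fs)
      sigma <- burst_duration_us(cfg) / 6  # edges at 3 sigma
      exp(-(t_us - tc)^2 / (2 * sigma^2))
    }
  )
  if (is.null(phases)) phases <- numeric(nrow(amps))
  s <- numeric(nb)
  for (i in seq_len(nrow(amps))) {
    s <- s + amps[i, 2] * sin(2 * pi * amps[i, 1] * cfg$f0 * t_us + phases[i])
  }
  s * env
}

# order/amplitude matrix implied by a config, with optional per-harmonic
# multipliers (replicate scatter) and a global amplitude scale
component_table <- function(cfg, multipliers = NULL, scale = 1) {
  orders <- as.numeric(names(cfg$harmonic_ratios))
  amps <- unname(cfg$harmonic_ratios)
  if (cfg$subharmonic_ratio > 0) {
    orders <- c(0.5, orders)
    amps <- c(cfg$subharmonic_ratio, amps)
  }
  if (!is.null(multipliers)) amps <- amps * multipliers
  cbind(order = orders, amplitude = amps * scale)
}

n_components <- function(cfg) {
  length(cfg$harmonic_ratios) + (cfg$subharmonic_ratio > 0)
}

# Assemble a full record from per-pulse bursts; uses the current RNG stream.
sim_record <- function(cfg, multipliers = NULL, scale = 1,
                       medium = "agent", replicate_id = 1L,
                       pressure_kPa = NA_real_) {
  amps <- component_table(cfg, multipliers, scale)
  phases <- if (cfg$random_phases) {
    stats::runif(nrow(amps), 0, 2 * pi)
  } else {
    NULL
  }
  burst <- make_burst(cfg, amps, phases)
  nb <- length(burst)
  ns <- as.integer(round(cfg$silence_us * cfg$fs))
  period <- as.integer(nb) + ns
  n <- cfg$n_pulses * period
  samples <- numeric(n)
  pulse_starts <- (seq_len(cfg$n_pulses) - 1L) * period + 1L
  for (p in pulse_starts) samples[p:(p + nb - 1L)] <- burst
  if (cfg$noise_rms > 0) {
    samples <- samples + stats::rnorm(n, sd = cfg$noise_rms)
  }
  structure(list(
    samples = samples, fs = cfg$fs, f0 = cfg$f0, n_cycles = cfg$n_cycles,
    pulse_starts = pulse_starts, medium = medium,
    pressure_kPa = pressure_kPa, replicate_id = as.integer(replicate_id),
    travel_time_us = cfg$travel_time_us, envelope = cfg$envelope
  ), class = "acquisition_record")
}

#' Simulate one side-scatter acquisition
#'
#' Generates an acquisition record emulating the side-scatter protocol: a
#' train of windowed tone bursts separated by silence, each containing
#' components at `k * f0` with the configured linear amplitude ratios (plus an
#' optional subharmonic at `f0 / 2`), on an additive white Gaussian noise
#' floor. Output is fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param medium medium label stored in the record (e.g. `"agent"`,
#'   `"saline"`).
#' @param replicate_id integer replicate identifier stored in the record.
#' @return An `acquisition_record`: sample waveform, sampling rate, transmit
#'   frequency, pulse start indices and metadata.
#' @export
simulate_scatter_acquisition <- function(cfg, medium = "agent",
                                         replicate_id = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, sim_record(cfg, medium = medium,
                                 replicate_id = replicate_id))
}

#' Simulate replicate side-scatter acquisitions
#'
#' Generates `cfg$n_replicates` acquisition records whose per-harmonic
#' amplitudes carry lognormal multiplicative scatter with coefficient of
#' variation `cfg$replicate_cv`, emulating repeated agent injections. The
#' lognormal keeps amplitudes positive and makes the derived dB statistics
#' approximately Gaussian across replicates.
#'
#' @inheritParams simulate_scatter_acquisition
#' @return A list of `acquisition_record` objects.
#' @export
simulate_scatter_replicates <- function(cfg, medium = "agent") {
  stopifnot(inherits(cfg, "sim_config"))
  sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  with_seed(cfg$seed, lapply(seq_len(cfg$n_replicates), function(i) {
    m <- if (sdlog > 0) {
      stats::rlnorm(n_components(cfg), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      NULL
    }
    sim_record(cfg, multipliers = m, medium = medium, replicate_id = i)
  }))
}

#' Simulate a through-transmission reference/agent record pair
#'
#' Emulates the insertion-loss protocol: a reference record (saline path) and
#' a medium record whose amplitude is scaled by
#' `10^(-alpha_true * d / 20)` relative to the reference, with the same noise
#' model. Feeding the pair to [estimate_attenuation()] recovers
#' `cfg$alpha_true`.
#'
#' @param cfg a [sim_config()]; `alpha_true` and `d` define the simulated
#'   medium.
#' @return A list with elements `reference` and `agent`, both
#'   `acquisition_record` objects.
#' @export
simulate_transmission_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  atten <- 10^(-cfg$alpha_true * cfg$d / 20)
  with_seed(cfg$seed, list(
    reference = sim_record(cfg, medium = "saline"),
    agent = sim_record(cfg, scale = atten, medium = "agent")
  ))
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf(
    "Acquisition record: %d pulses, %d samples at %g MHz (medium '%s')\n",
    length(x$pulse_starts), length(x$samples), x$fs, x$medium))
  cat(sprintf("  f0 %g MHz, %d cycles, replicate %d\n",
              x$f0, x$n_cycles, x$replicate_id))
  invisible(x)
}

#' @export
as.data.frame.acquisition_record <- function(x, ...) {
  data.frame(time_us = (seq_along(x$samples) - 1) / x$fs,
             amplitude = x$samples)
}

#' Triangular indicator-dilution concentration curve
#'
#' Concentration at the measurement site under the triangular bolus model:
#' zero before arrival, a linear rise to the peak and a linear fall back to
#' zero over the transit duration. Only the base duration and mass
#' conservation constrain the triangle, giving peak concentration
#' `C_peak = 2 * dose / (Q * T_b)` so that the time integral equals
#' `dose / Q` exactly.
#'
#' @param t time points (s).
#' @param bolus a [bolus_config()].
#' @param apex_frac position of the apex as a fraction of the transit
#'   duration (shape parameter; does not affect the peak value or integral).
#' @return Concentration (mg/mL) at each `t`.
#' @export
triangular_concentration <- function(t, bolus, apex_frac = 0.5) {
  stopifnot(inherits(bolus, "bolus_config"))
  if (apex_frac <= 0 || apex_frac >= 1) stop("apex_frac must be in (0, 1)")
  q_s <- bolus$flow / 60                       # mL/s
  c_peak <- 2 * bolus$dose / (q_s * bolus$transit_duration)
  t0 <- bolus$arrival_time
  tb <- bolus$transit_duration
  ta <- t0 + apex_frac * tb
  t1 <- t0 + tb
  conc <- numeric(length(t))
  rise <- t >= t0 & t < ta
  fall <- t >= ta & t <= t1
  conc[rise] <- c_peak * (t[rise] - t0) / (ta - t0)
  conc[fall] <- c_peak * (t1 - t[fall]) / (t1 - ta)
  conc
}

#' Simulate a DCE-US clip of a contrast bolus
#'
#' Generates per-frame responses to the three-pulse contrast scheme
#' (amplitudes `[1, -0.5, -0.5]` by default). Each frame holds three RF-like
#' signed images: a static linear scatter field (the phantom) scaled by the
#' transmit amplitude, a nonlinear component scaling with the square of the
#' transmit amplitude and with the local agent concentration from the
#' triangular bolus model modulated by pulsatility, and white noise. Because
#' the linear component is exactly proportional to transmit amplitude it
#' cancels in the scheme combination ([combine_pulses()]).
#'
#' The nonlinear RF amplitude is proportional to the square root of
#' `response(concentration)`, so the linearized (squared-envelope) intensity
#' extracted by [extract_tic()] is proportional to `response(concentration)`;
#' with the default identity response the TIC is linear in concentration.
#'
#' @param cfg a [sim_config()]; supplies `noise_rms` and `seed`.
#' @param bolus a [bolus_config()].
#' @param response monotone nondecreasing function mapping concentration to
#'   linearized ROI signal; default identity (linear regime).
#' @param dim image size `c(ny, nx)` in pixels.
#' @param scheme a [pulse_scheme()].
#' @param perfused logical `ny x nx` mask of perfused pixels; default is a
#'   central horizontal band covering half the image.
#' @param phantom_seed seed for the static scatter fields. Clips sharing
#'   `phantom_seed` image the same phantom realization (as repeated boluses
#'   through one phantom do); defaults to `cfg$seed`.
#' @return A `dceus_clip`: arrays `p1`, `p2`, `p3` of size `ny x nx x nt`,
#'   frame times, the scheme, the bolus, the perfusion mask and the
#'   ground-truth concentration per frame.
#' @export
simulate_dceus_clip <- function(cfg, bolus, response = identity,
                                dim = c(64, 64), scheme = pulse_scheme(),
                                perfused = NULL, phantom_seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), inherits(bolus, "bolus_config"))
  ny <- dim[1]; nx <- dim[2]
  nt <- floor(bolus$clip_duration * bolus$frame_rate)
  times <- (seq_len(nt) - 1) / bolus$frame_rate
  conc <- triangular_concentration(times, bolus)
  if (bolus$pulsatility_amp > 0) {
    conc <- conc * (1 + bolus$pulsatility_amp *
                      sin(2 * pi * bolus$pulsatility_freq * times))
  }
  sig <- response(conc)
  if (any(diff(response(seq(0, max(conc) + 1e-12, length.out = 64))) < -1e-12)) {
    stop("response curve must be monotone nondecreasing", call. = FALSE)
  }
  if (any(sig < 0)) stop("response curve must be nonnegative", call. = FALSE)
  if (is.null(perfused)) {
    perfused <- matrix(FALSE, ny, nx)
    band <- max(1L, floor(ny / 4)):min(ny, ceiling(3 * ny / 4))
    perfused[band, ] <- TRUE
  }
  fields <- with_seed(phantom_seed, list(
    linear = matrix(stats::rnorm(ny * nx), ny, nx),
    nonlinear = matrix(stats::rnorm(ny * nx), ny, nx) * perfused
  ))
  amps <- scheme$amplitudes
  p <- lapply(1:3, function(k) array(0, c(ny, nx, nt)))
  with_seed(cfg$seed, {
    for (i in seq_len(nt)) {
      nl <- sqrt(sig[i]) * fields$nonlinear
      for (k in 1:3) {
        frame <- amps[k] * fields$linear + amps[k]^2 * nl
        if (cfg$noise_rms > 0) {
          frame <- frame + matrix(stats::rnorm(ny * nx, sd = cfg$noise_rms),
                                  ny, nx)
        }
        p[[k]][, , i] <- frame
      }
    }
  })
  structure(list(
    p1 = p[[1]], p2 = p[[2]], p3 = p[[3]], times = times, scheme = scheme,
    bolus = bolus, perfused = perfused, concentration = conc,
    dim = c(ny, nx)
  ), class = "dceus_clip")
}

#' @export
print.dceus_clip <- function(x, ...) {
  cat(sprintf("DCE-US clip: %d frames of %d x %d pixels over %.1f s\n",
              length(x$times), x$dim[1], x$dim[2], max(x$times)))
  cat(sprintf("  scheme amplitudes [%s], dose %g mg\n",
              paste(x$scheme$amplitudes, collapse = ", "), x$bolus$dose))
  invisible(x)
}
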