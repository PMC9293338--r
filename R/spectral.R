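# Averaged amplitude spectra and harmonic side-scatter statistics.

#' Segment an acquisition into per-pulse analysis windows
#'
#' Cuts one fixed-length analysis window per pulse, starting a fixed offset
#' after each pulse start. The default offset is the acoustic travel time
#' stored in the record metadata, a deterministic stand-in for the manual
#' window placement used in practice; the default window length is 9 us, the
#' duration of the shortest scattered signal in the characterization study.
#'
#' @param rec an `acquisition_record`.
#' @param window_us analysis window length (microseconds).
#' @param offset_us window start offset after each pulse start; defaults to
#'   the record's `travel_time_us`.
#' @return A numeric matrix with one column per pulse (class
#'   `pulse_segments`), each of exactly `round(window_us * fs)` rows, with
#'   the record's `fs`, `f0` and `n_cycles` attached as attributes.
#' @export
segment_pulses <- function(rec, window_us = 9, offset_us = NULL) {
  stopifnot(inherits(rec, "acquisition_record"))
  offset_us <- offset_us %||% rec$travel_time_us
  len <- round(window_us * rec$fs)
  if (len < 2) stop("analysis window too short", call. = FALSE)
  off <- round(offset_us * rec$fs)
  spacing <- if (length(rec$pulse_starts) > 1) {
    min(diff(rec$pulse_starts))
  } else {
    length(rec$samples) - rec$pulse_starts[1] + 1L
  }
  if (off + len > spacing) {
    stop("segment overrun: window exceeds inter-pulse spacing", call. = FALSE)
  }
  last_end <- rec$pulse_starts[length(rec$pulse_starts)] + off + len - 1L
  if (last_end > length(rec$samples)) {
    stop("segment overrun: window extends past the end of the record",
         call. = FALSE)
  }
  seg <- vapply(rec$pulse_starts,
                function(p) rec$samples[(p + off):(p + off + len - 1L)],
                numeric(len))
  structure(seg, class = "pulse_segments",
            fs = rec$fs, f0 = rec$f0, n_cycles = rec$n_cycles,
            window_us = len / rec$fs)
}

#' Averaged amplitude spectrum of pulse segments
#'
#' Applies a taper to every segment, computes the magnitude of its discrete
#' Fourier transform and averages the amplitude (not power) spectra over all
#' pulses, as in the side-scatter analysis protocol. The default taper is a
#' periodic Hann window, reducing spectral leakage.
#'
#' @param segments a `pulse_segments` matrix from [segment_pulses()] (or any
#'   matrix with one segment per column, with `fs` supplied).
#' @param window taper name: `"hanning"` (default), `"rectangular"` or
#'   `"hamming"`.
#' @param fs sampling rate (MHz); taken from the segment attributes when
#'   present.
#' @return A `uca_spectrum`: one-sided frequency grid (MHz), mean amplitude
#'   per frequency (linear units), number of pulses averaged, window name and
#'   segment metadata.
#' @export
averaged_amplitude_spectrum <- function(segments, window = "hanning",
                                        fs = attr(segments, "fs")) {
  if (is.list(segments)) {
    if (length(segments) == 0) stop("empty segment list", call. = FALSE)
    lens <- lengths(segments)
    if (length(unique(lens)) != 1) {
      stop("all segments must have equal length", call. = FALSE)
    }
    segments <- matrix(unlist(segments), nrow = lens[1])
  }
  if (is.null(dim(segments))) segments <- matrix(segments, ncol = 1)
  if (ncol(segments) == 0) stop("empty segment list", call. = FALSE)
  if (is.null(fs)) stop("sampling rate 'fs' required", call. = FALSE)
  n <- nrow(segments)
  w <- taper_window(n, window)
  mags <- Mod(stats::mvfft(segments * w))
  keep <- seq_len(floor(n / 2) + 1)
  structure(list(
    freqs = (keep - 1) * fs / n,
    amplitude = rowMeans(mags)[keep],
    fs = fs, n = n,
    n_pulses_averaged = ncol(segments),
    segment_length_us = n / fs,
    window = window,
    f0 = attr(segments, "f0"),
    n_cycles = attr(segments, "n_cycles")
  ), class = "uca_spectrum")
}

#' @export
print.uca_spectrum <- function(x, ...) {
  cat(sprintf(
    "Averaged amplitude spectrum: %d bins to %.2f MHz (df = %.4f MHz)\n",
    length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  cat(sprintf("  %d pulses averaged, %s window, %.2f us segments\n",
              x$n_pulses_averaged, x$window, x$segment_length_us))
  invisible(x)
}

#' @export
plot.uca_spectrum <- function(x, db = TRUE, ...) {
  y <- if (db) 20 * log10(x$amplitude / max(x$amplitude)) else x$amplitude
  graphics::plot(x$freqs, y, type = "l", xlab = "Frequency (MHz)",
                 ylab = if (db) "Amplitude (dB re max)" else "Amplitude",
                 ...)
  invisible(x)
}

# Hann main-lobe gain at a fractional bin offset (asymptotic in segment length)
hann_line_gain <- function(delta) {
  ifelse(abs(delta) < 1e-9, 1,
         sin(pi * delta) / (pi * delta) / (1 - delta^2))
}

# Grandke two-bin interpolation of a Hann-windowed line around peak bin p:
# returns the scalloping-corrected amplitude.
grandke_amplitude <- function(amp, p) {
  if (p <= 1L || p >= length(amp)) return(amp[p])
  if (amp[p + 1] >= amp[p - 1]) {
    beta <- amp[p + 1] / amp[p]
    delta <- (2 * beta - 1) / (beta + 1)
  } else {
    beta <- amp[p - 1] / amp[p]
    delta <- -(2 * beta - 1) / (beta + 1)
  }
  if (!is.finite(delta)) delta <- 0
  delta <- max(min(delta, 0.5), -0.5)
  amp[p] / hann_line_gain(delta)
}

#' Extract harmonic amplitudes from an averaged spectrum
#'
#' Locates, for every requested order (0.5 marks the subharmonic), the
#' spectral peak within `order * f0 +/- search_halfwidth` and reports its
#' amplitude, together with the two nonlinear side-scatter statistics: the
#' amplitude relative to a saline reference spectrum at the same frequency
#' (`snonl_saline_dB`) and the amplitude relative to the fundamental of the
#' same spectrum (`snonl_fund_dB`), both on the `10*log10` amplitude-ratio
#' scale used in the characterization study (see [snonl_vs_saline()]).
#'
#' The default `method = "interp"` refines the peak-bin amplitude by Grandke
#' two-bin interpolation with the Hann main-lobe gain correction, removing
#' the up to ~1.4 dB scalloping bias that the raw maximum suffers when a
#' harmonic does not fall on a bin centre. `method = "peak"` reports the raw
#' maximum; `method = "rss"` the root-sum-square amplitude over the search
#' band (robust to line-shape distortion, relative units).
#'
#' @param spec a `uca_spectrum`.
#' @param f0 fundamental (transmit) frequency in MHz; defaults to the value
#'   carried by the spectrum.
#' @param orders harmonic orders to extract; supports `0.5` for the
#'   subharmonic.
#' @param search_halfwidth half-width of the search band in MHz; default
#'   `f0 / n_cycles`, half the -6 dB bandwidth of the transmit burst.
#' @param method amplitude estimator, see Details.
#' @param ref optional saline reference `uca_spectrum` on the same frequency
#'   grid, enabling the `snonl_saline_dB` column.
#' @param convention dB convention for the nonlinear statistics, 10 (as used
#'   in the study) or 20 (conventional amplitude decibels).
#' @return A `harmonic_table` data frame: `order`, `freq`, `amplitude`,
#'   `snonl_fund_dB` and, when `ref` is given, `snonl_saline_dB`.
#' @export
extract_harmonics <- function(spec, f0 = spec$f0, orders = c(1, 2, 3),
                              search_halfwidth = NULL,
                              method = c("interp", "peak", "rss"),
                              ref = NULL, convention = 10) {
  stopifnot(inherits(spec, "uca_spectrum"))
  method <- match.arg(method)
  if (is.null(f0)) stop("f0 required", call. = FALSE)
  check_scalar(f0, "f0", positive = TRUE)
  search_halfwidth <- search_halfwidth %||%
    (f0 / (spec$n_cycles %||% 10))
  nyq <- spec$fs / 2
  if (max(orders) * f0 > nyq) {
    stop(sprintf("Nyquist violation: order %g at %g MHz exceeds %g MHz",
                 max(orders), max(orders) * f0, nyq), call. = FALSE)
  }
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "uca_spectrum"))
    if (length(ref$freqs) != length(spec$freqs) ||
        any(abs(ref$freqs - spec$freqs) > 1e-9)) {
      stop("reference spectrum must share the frequency grid", call. = FALSE)
    }
  }
  amp <- spec$amplitude
  rows <- lapply(orders, function(o) {
    target <- o * f0
    band <- which(abs(spec$freqs - target) <= search_halfwidth)
    if (length(band) == 0) {
      band <- which.min(abs(spec$freqs - target))  # halfwidth below bin width
    }
    p <- band[which.max(amp[band])]
    a <- switch(method,
      peak = amp[p],
      interp = grandke_amplitude(amp, p),
      rss = sqrt(sum(amp[band]^2))
    )
    list(order = o, freq = spec$freqs[p], amplitude = a,
         ref_amplitude = if (!is.null(ref)) ref$amplitude[p] else NA_real_)
  })
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  a_fund <- tab$amplitude[tab$order == 1]
  if (length(a_fund) == 1 && a_fund > 0) {
    tab$snonl_fund_dB <- snonl_vs_fundamental(tab$amplitude, a_fund,
                                              convention = convention)
    tab$snonl_fund_dB[tab$order == 1] <- 0   # exact by construction
  } else {
    tab$snonl_fund_dB <- NA_real_
  }
  if (!is.null(ref)) {
    tab$snonl_saline_dB <- snonl_vs_saline(tab$amplitude, tab$ref_amplitude,
                                           convention = convention)
  }
  tab$ref_amplitude <- NULL
  structure(tab, class = c("harmonic_table", "data.frame"),
            f0 = f0, convention = convention, method = method)
}

check_convention <- function(convention) {
  if (!(length(convention) == 1 && convention %in% c(10, 20))) {
    stop("convention must be 10 (study convention) or 20", call. = FALSE)
  }
  convention
}

#' Nonlinear scatter relative to the saline reference
#'
#' Side-scatter statistic comparing the agent spectrum to the saline (noise
#' floor) spectrum at the same frequency:
#' `S_nonl(f) = 10 * log10(A_CA(f) / A_sal(f))`. The study's printed
#' `10*log10` amplitude-ratio convention is the default; `convention = 20`
#' gives conventional amplitude decibels.
#'
#' @param a_ca agent amplitude(s) at frequency f (linear units).
#' @param a_sal saline reference amplitude(s) at the same frequency; must be
#'   positive.
#' @param convention 10 or 20.
#' @return Statistic in dB.
#' @export
snonl_vs_saline <- function(a_ca, a_sal, convention = 10) {
  check_convention(convention)
  if (any(a_sal <= 0)) stop("reference amplitude must be positive",
                            call. = FALSE)
  if (any(a_ca < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  convention * log10(a_ca / a_sal)
}

#' Nonlinear scatter relative to the fundamental
#'
#' Side-scatter statistic normalizing the spectrum by its own fundamental
#' amplitude: `S_nonl(f) = 10 * log10(A_CA(f) / A_CA(f0))`; the value at the
#' fundamental is 0 by construction. This normalization mitigates the
#' influence of bubble concentration and size on the compared spectra.
#'
#' @param a_f amplitude(s) at frequency f (linear units).
#' @param a_f0 amplitude at the fundamental; must be positive.
#' @inheritParams snonl_vs_saline
#' @return Statistic in dB.
#' @export
snonl_vs_fundamental <- function(a_f, a_f0, convention = 10) {
  check_convention(convention)
  if (any(a_f0 <= 0)) stop("fundamental amplitude must be positive",
                           call. = FALSE)
  if (any(a_f < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  convention * log10(a_f / a_f0)
}

#' Aggregate harmonic tables over replicate acquisitions
#'
#' Per-order mean and sample standard deviation (denominator n - 1) of a
#' chosen dB statistic over replicate acquisitions, mirroring the 15-replicate
#' aggregation of the characterization protocol.
#'
#' @param tables list of `harmonic_table` objects with identical orders.
#' @param statistic column to aggregate: `"snonl_fund_dB"`,
#'   `"snonl_saline_dB"` or `"amplitude"`.
#' @return A `replicate_summary` data frame: `order`, `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(tables, statistic = c("snonl_fund_dB",
                                                       "snonl_saline_dB",
                                                       "amplitude")) {
  statistic <- match.arg(statistic)
  if (length(tables) < 2) stop("need at least 2 replicate tables",
                               call. = FALSE)
  orders <- tables[[1]]$order
  for (tb in tables) {
    if (!identical(tb$order, orders)) {
      stop("mismatched orders across replicate tables", call. = FALSE)
    }
    if (!statistic %in% names(tb)) {
      stop(sprintf("statistic '%s' missing from a table", statistic),
           call. = FALSE)
    }
  }
  vals <- vapply(tables, function(tb) tb[[statistic]], numeric(length(orders)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  out <- data.frame(order = orders,
                    mean = rowMeans(vals),
                    sd = apply(vals, 1, stats::sd),
                    n = length(tables))
  structure(out, class = c("replicate_summary", "data.frame"),
            statistic = statistic)
}

#' Compare a harmonic statistic between two agents
#'
#' Two-sample two-sided t test of per-replicate values (e.g. one harmonic's
#' dB statistic) between two agents. The default is the pooled-variance
#' Student test, assuming Gaussian-distributed replicate values; Welch's
#' unequal-variance variant is available. Identical zero-variance groups give
#' p = 1 (zero t statistic); zero-variance groups with different means give
#' p = 0 (the limit of the statistic). No multiple-testing correction is
#' applied; significance is flagged at p < 0.05.
#'
#' @param a,b numeric vectors of per-replicate values, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead of the pooled test.
#' @param alpha significance threshold for the flag.
#' @return A list: `p_value`, `statistic`, `df`, `significant`.
#' @export
compare_agents_ttest <- function(a, b, welch = FALSE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(p_value = p, statistic = if (p == 1) 0 else Inf,
                df = length(a) + length(b) - 2, significant = p < alpha))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       df = unname(ht$parameter), significant = unname(ht$p.value) < alpha)
}
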