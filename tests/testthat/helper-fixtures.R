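# shared fixtures: all synthetic, built in code

# acquisition record built directly (bypasses the generators)
make_record <- function(samples, fs = 25, f0 = 1, n_cycles = 10,
                        pulse_starts = 1L, medium = "agent",
                        travel_time_us = 0) {
  structure(list(
    samples = samples, fs = fs, f0 = f0, n_cycles = n_cycles,
    pulse_starts = as.integer(pulse_starts), medium = medium,
    pressure_kPa = NA_real_, replicate_id = 1L,
    travel_time_us = travel_time_us, envelope = "rectangular"
  ), class = "acquisition_record")
}

# analysis window following the study's rule: never longer than the signal
window_for <- function(cfg) min(9, burst_duration_us(cfg))

harmonics_of <- function(cfg, orders = c(1, 2, 3), ...) {
  rec <- simulate_scatter_acquisition(cfg)
  spec <- averaged_amplitude_spectrum(segment_pulses(rec, window_for(cfg)))
  extract_harmonics(spec, orders = orders, ...)
}

# exhaustive two-sample permutation test on the pooled t statistic
perm_ttest_p <- function(a, b) {
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  all_vals <- c(a, b)
  t_obs <- abs(pooled_t(a, b))
  splits <- utils::combn(length(all_vals), length(a))
  t_perm <- apply(splits, 2, function(ix) {
    abs(pooled_t(all_vals[ix], all_vals[-ix]))
  })
  mean(t_perm >= t_obs - 1e-12)
}
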