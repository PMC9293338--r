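test_that("segmentation yields one fixed-length window per pulse", {
  cfg <- sim_config(f0 = 1, n_cycles = 10, n_pulses = 93, noise_rms = 0)
  rec <- simulate_scatter_acquisition(cfg)
  seg <- segment_pulses(rec, window_us = 9)
  expect_equal(dim(seg), c(225, 93))   # 9 us * 25 MHz = 225 samples
  # a window longer than burst + silence must be refused
  expect_error(segment_pulses(rec, window_us = 300), "overrun")
  # constant-zero record -> all-zero segments
  zero <- make_record(numeric(3000), pulse_starts = c(1L, 1001L, 2001L))
  expect_true(all(segment_pulses(zero, window_us = 9) == 0))
})

test_that("averaged spectrum is the mean of per-segment amplitude spectra", {
  s <- sin(2 * pi * 1 * (0:224) / 25)
  one <- averaged_amplitude_spectrum(matrix(s, ncol = 1), fs = 25)
  many <- averaged_amplitude_spectrum(matrix(rep(s, 5), ncol = 5), fs = 25)
  expect_equal(many$amplitude, one$amplitude)
  expect_equal(many$n_pulses_averaged, 5)
  # all-zero segments -> all-zero amplitude
  z <- averaged_amplitude_spectrum(matrix(0, 225, 3), fs = 25)
  expect_true(all(z$amplitude == 0))
  expect_error(averaged_amplitude_spectrum(list()), "empty")
})

test_that("spectrum is linear in input amplitude", {
  set.seed(8)
  seg <- matrix(rnorm(225 * 4), 225, 4)
  s1 <- averaged_amplitude_spectrum(seg, fs = 25)
  s3 <- averaged_amplitude_spectrum(3 * seg, fs = 25)
  expect_equal(s3$amplitude, 3 * s1$amplitude)
})

test_that("Hann taper gives the closed-form line shape at a bin centre", {
  # periodic Hann: a bin-centred tone has neighbours at exactly half the peak
  n <- 225
  m <- 9                       # 1 MHz at fs = 25 MHz
  s <- sin(2 * pi * m * (0:(n - 1)) / n)
  spec <- averaged_amplitude_spectrum(matrix(s, ncol = 1), fs = 25)
  peak <- spec$amplitude[m + 1]
  expect_equal(spec$amplitude[m] / peak, 0.5, tolerance = 1e-9)
  expect_equal(spec$amplitude[m + 2] / peak, 0.5, tolerance = 1e-9)
  # coherent gain of Hann is 1/2: peak = A * N / 4
  expect_equal(peak, n / 4, tolerance = 1e-9)
})

test_that("harmonic extraction recovers amplitudes and handles edge rules", {
  cfg <- sim_config(f0 = 2.25, n_cycles = 20,
                    harmonic_ratios = c("1" = 1, "2" = 0.1), noise_rms = 0)
  rec <- simulate_scatter_acquisition(cfg)
  spec <- averaged_amplitude_spectrum(segment_pulses(rec, window_for(cfg)))
  tab <- extract_harmonics(spec, orders = c(1, 2))
  expect_equal(tab$amplitude[2] / tab$amplitude[1], 0.1, tolerance = 0.01)
  # zero halfwidth falls back to the nearest grid bin
  tab0 <- extract_harmonics(spec, orders = 1, search_halfwidth = 0,
                            method = "peak")
  i <- which.min(abs(spec$freqs - 2.25))
  expect_equal(tab0$amplitude, spec$amplitude[i])
  # beyond-Nyquist orders are refused
  expect_error(extract_harmonics(spec, orders = c(1, 6)), "Nyquist")
  # absent subharmonic reads at noise-floor level
  cfgn <- sim_config(f0 = 2, n_cycles = 20, noise_rms = 0.001, seed = 3)
  tabn <- harmonics_of(cfgn, orders = c(0.5, 1))
  expect_lt(tabn$amplitude[tabn$order == 0.5] /
              tabn$amplitude[tabn$order == 1], 0.01)
})

test_that("nonlinear scatter statistics follow the printed dB definitions", {
  expect_equal(snonl_vs_saline(1, 1), 0)
  expect_equal(snonl_vs_saline(10, 1), 10)
  expect_equal(snonl_vs_saline(2, 1), 10 * log10(2))  # 3.0103 dB
  expect_equal(snonl_vs_fundamental(1, 1), 0)
  expect_equal(snonl_vs_fundamental(0.1, 1), -10)
  expect_equal(snonl_vs_fundamental(0.5, 1), -10 * log10(2))
  # flagged conventional amplitude-dB variant
  expect_equal(snonl_vs_saline(10, 1, convention = 20), 20)
  expect_error(snonl_vs_saline(1, 0), "positive")
  expect_error(snonl_vs_fundamental(1, -2), "positive")
})

test_that("scatter statistics are additive under amplitude scaling", {
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, 0.01, 10)
    ref <- runif(1, 0.01, 10)
    cc <- runif(1, 0.1, 100)
    expect_equal(snonl_vs_saline(cc * a, ref),
                 snonl_vs_saline(a, ref) + 10 * log10(cc))
    expect_equal(snonl_vs_fundamental(cc * a, ref),
                 snonl_vs_fundamental(a, ref) + 10 * log10(cc))
  }
})

test_that("the fundamental's normalized statistic is exactly zero", {
  set.seed(2)
  for (i in 1:10) {
    cfg <- sim_config(f0 = runif(1, 0.8, 2.5), n_cycles = 10,
                      harmonic_ratios = c("1" = 1, "2" = runif(1, 0, 0.5)),
                      noise_rms = runif(1, 0, 0.05), seed = i)
    tab <- harmonics_of(cfg, orders = c(1, 2))
    expect_identical(tab$snonl_fund_dB[tab$order == 1], 0)
  }
})

test_that("replicate aggregation gives per-order mean and sample sd", {
  tab1 <- data.frame(order = c(1, 2), snonl_fund_dB = c(0, -10))
  tab2 <- data.frame(order = c(1, 2), snonl_fund_dB = c(0, -12))
  s <- summarize_replicates(list(tab1, tab2))
  expect_equal(s$mean, c(0, -11))
  expect_equal(s$sd, c(0, abs(-10 - (-12)) / sqrt(2)))
  expect_equal(s$n, c(2, 2))
  # identical tables: zero sd
  s0 <- summarize_replicates(list(tab1, tab1, tab1))
  expect_equal(s0$sd, c(0, 0))
  expect_error(summarize_replicates(list(tab1)), "at least 2")
  tab3 <- data.frame(order = c(1, 3), snonl_fund_dB = c(0, -9))
  expect_error(summarize_replicates(list(tab1, tab3)), "mismatched")
})

test_that("replicate mean concentrates as the sampling distribution predicts", {
  mu <- -8; sigma <- 1.5
  set.seed(99)
  tabs <- lapply(1:15, function(i) {
    data.frame(order = 2, snonl_fund_dB = rnorm(1, mu, sigma))
  })
  s <- summarize_replicates(tabs)
  expect_lt(abs(s$mean - mu), 4 * sigma / sqrt(15))
})

test_that("agent comparison t-test behaves at its extremes", {
  a <- c(1, 2, 3)
  expect_equal(compare_agents_ttest(a, a)$p_value, 1)
  shifted <- compare_agents_ttest(a, a + 100)
  expect_lt(shifted$p_value, 0.001)
  expect_true(shifted$significant)
  # constant but different groups: limiting p of an infinite statistic
  expect_equal(compare_agents_ttest(c(2, 2), c(5, 5))$p_value, 0)
  expect_error(compare_agents_ttest(1, c(1, 2)), "at least 2")
})

test_that("pooled t-test agrees with an exhaustive permutation oracle", {
  a <- c(1.8, 3.1, 2.4, 2.9, 1.6)
  b <- c(2.6, 3.8, 3.3, 2.2, 3.9)
  p_t <- compare_agents_ttest(a, b)$p_value
  p_perm <- perm_ttest_p(a, b)           # resolution 1/choose(10,5)
  expect_lt(abs(p_t - p_perm), 0.06)
  # Welch variant stays close to the pooled test for balanced groups
  expect_equal(compare_agents_ttest(a, b, welch = TRUE)$p_value, p_t,
               tolerance = 0.02)
})

test_that("snonl_saline reports agent-to-reference spectrum contrast", {
  cfg_ag <- sim_config(f0 = 1, n_cycles = 10,
                       harmonic_ratios = c("1" = 1, "2" = 0.2),
                       noise_rms = 0.001, seed = 31)
  cfg_sal <- sim_config(f0 = 1, n_cycles = 10, harmonic_ratios = c("1" = 1),
                        noise_rms = 0.001, seed = 32)
  rec_ag <- simulate_scatter_acquisition(cfg_ag)
  # saline reference: noise only (no scattered burst) on the same grid
  rec_sal <- simulate_scatter_acquisition(cfg_sal)
  set.seed(32)
  rec_sal$samples <- rnorm(length(rec_sal$samples), sd = 0.001)
  spec_ag <- averaged_amplitude_spectrum(segment_pulses(rec_ag, 9))
  spec_sal <- averaged_amplitude_spectrum(segment_pulses(rec_sal, 9))
  tab <- extract_harmonics(spec_ag, orders = c(1, 2), ref = spec_sal)
  # agent harmonics stand far above the saline noise floor
  expect_true(all(tab$snonl_saline_dB > 10))
  expect_gt(tab$snonl_saline_dB[1], tab$snonl_saline_dB[2])
})
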