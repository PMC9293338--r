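test_that("config validation enforces protocol invariants", {
  expect_error(sim_config(f0 = -1), "f0")
  expect_error(sim_config(n_pulses = 50), "92")
  expect_error(sim_config(harmonic_ratios = c("1" = 1, "2" = -0.1)),
               "nonnegative")
  expect_error(sim_config(harmonic_ratios = c("2" = 0.1)), "order 1")
  # fs must exceed twice the highest harmonic frequency
  expect_error(sim_config(f0 = 3.5, harmonic_ratios = c("1" = 1, "4" = 0.1)),
               "aliasing")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(noise_rms = 0.05, seed = 42)
  expect_identical(simulate_scatter_acquisition(cfg)$samples,
                   simulate_scatter_acquisition(cfg)$samples)
  p1 <- simulate_transmission_pair(cfg)
  p2 <- simulate_transmission_pair(cfg)
  expect_identical(p1$reference$samples, p2$reference$samples)
  expect_identical(p1$agent$samples, p2$agent$samples)
  cfg2 <- sim_config(noise_rms = 0.05, seed = 43)
  expect_false(identical(simulate_scatter_acquisition(cfg2)$samples,
                         simulate_scatter_acquisition(cfg)$samples))
})

test_that("a pure tone has second-harmonic content only at leakage level", {
  cfg <- sim_config(f0 = 1, n_cycles = 10, harmonic_ratios = c("1" = 1),
                    noise_rms = 0)
  tab <- harmonics_of(cfg, orders = c(1, 2), method = "peak")
  # amplitude dB below the fundamental
  rel_db <- 20 * log10(tab$amplitude[2] / tab$amplitude[1])
  expect_lt(rel_db, -60)
})

test_that("prescribed harmonic ratios are recovered by the spectral module", {
  # closed-form expectation: ratio of the two line amplitudes
  for (f0_nc in list(c(1, 10), c(2.25, 20), c(3.5, 20))) {
    cfg <- sim_config(f0 = f0_nc[1], n_cycles = f0_nc[2],
                      harmonic_ratios = c("1" = 1, "2" = 0.1), noise_rms = 0)
    tab <- harmonics_of(cfg, orders = c(1, 2))
    ratio <- tab$amplitude[2] / tab$amplitude[1]
    expect_equal(ratio, 0.1, tolerance = 0.01)
  }
})

test_that("subharmonic component appears at f0/2 when configured", {
  cfg <- sim_config(f0 = 2, n_cycles = 20, subharmonic_ratio = 0.2,
                    noise_rms = 0)
  tab <- harmonics_of(cfg, orders = c(0.5, 1))
  expect_equal(tab$amplitude[tab$order == 0.5] /
                 tab$amplitude[tab$order == 1], 0.2, tolerance = 0.01)
})

test_that("transmission pair scales the medium record by the configured loss", {
  # 20*log10(2) = 6.0206 dB over 1 cm halves the amplitude
  cfg <- sim_config(alpha_true = 20 * log10(2), d = 1, noise_rms = 0)
  pair <- simulate_transmission_pair(cfg)
  a_ref <- fundamental_amplitude(pair$reference, window_for(cfg))
  a_ca <- fundamental_amplitude(pair$agent, window_for(cfg))
  expect_equal(a_ref / a_ca, 2, tolerance = 1e-6)

  cfg0 <- sim_config(alpha_true = 0, noise_rms = 0)
  pair0 <- simulate_transmission_pair(cfg0)
  expect_equal(fundamental_amplitude(pair0$reference, window_for(cfg0)),
               fundamental_amplitude(pair0$agent, window_for(cfg0)),
               tolerance = 1e-9)
})

test_that("replicate records carry lognormal amplitude scatter", {
  cfg <- sim_config(n_replicates = 15, replicate_cv = 0.1, noise_rms = 0,
                    seed = 11)
  recs <- simulate_scatter_replicates(cfg)
  expect_length(recs, 15)
  expect_identical(vapply(recs, function(r) r$replicate_id, integer(1)),
                   1:15)
  amps <- vapply(recs, fundamental_amplitude, numeric(1),
                 window_us = window_for(cfg))
  expect_true(all(amps > 0))
  expect_gt(stats::sd(amps) / mean(amps), 0.02)   # scatter present
  expect_lt(stats::sd(amps) / mean(amps), 0.3)    # of the right magnitude
})

test_that("triangular concentration conserves injected mass", {
  bolus <- bolus_config(dose = 0.5, flow = 36, transit_duration = 10,
                        arrival_time = 3, clip_duration = 40)
  # algebraic identity: C_peak * T_b / 2 * Q = dose
  c_peak <- max(triangular_concentration(seq(0, 20, by = 1e-3), bolus))
  expect_equal(c_peak * 10 / 2 * (36 / 60), 0.5, tolerance = 1e-3)
  # numerical integral equals dose / flow
  t <- seq(0, 40, by = 1e-3)
  conc <- triangular_concentration(t, bolus)
  integral <- sum((conc[-1] + conc[-length(conc)]) / 2) * 1e-3
  expect_equal(integral, 0.5 / (36 / 60), tolerance = 1e-5)
})

test_that("DCE-US generator responds to dose as designed", {
  cfg <- sim_config(noise_rms = 0.02, seed = 5)
  # zero dose: flat TIC at noise level
  clip0 <- simulate_dceus_clip(cfg, bolus_config(dose = 0, frame_rate = 5),
                               dim = c(24, 24))
  tic0 <- extract_tic(clip0)
  noise_floor <- stats::median(tic0$intensity)
  expect_lt(max(tic0$intensity), 3 * noise_floor + 1e-12)

  # no pulsatility: smooth rise then fall around the apex
  bol <- bolus_config(pulsatility_amp = 0, frame_rate = 5)
  clip <- simulate_dceus_clip(sim_config(noise_rms = 0, seed = 5), bol,
                              dim = c(24, 24))
  tic <- extract_tic(clip, roi = c(4, 8, 20, 16))
  apex <- bol$arrival_time + bol$transit_duration / 2
  expect_lt(abs(tic$peak_time - apex), 1 / bol$frame_rate + 1e-9)
  rising <- tic$t > bol$arrival_time + 1 & tic$t < apex - 1
  falling <- tic$t > apex + 1 &
    tic$t < bol$arrival_time + bol$transit_duration - 1
  expect_true(all(diff(tic$intensity[rising]) > 0))
  expect_true(all(diff(tic$intensity[falling]) < 0))
})

test_that("clips sharing a phantom are reproducible and dose-linear", {
  cfg <- sim_config(noise_rms = 0.01, seed = 21)
  bolA <- bolus_config(dose = 0.5, frame_rate = 5)
  bolB <- bolus_config(dose = 1.0, frame_rate = 5)
  c1 <- simulate_dceus_clip(cfg, bolA, dim = c(24, 24), phantom_seed = 99)
  c2 <- simulate_dceus_clip(cfg, bolA, dim = c(24, 24), phantom_seed = 99)
  expect_identical(c1$p1, c2$p1)
  cfg2 <- sim_config(noise_rms = 0.01, seed = 22)
  c3 <- simulate_dceus_clip(cfg2, bolB, dim = c(24, 24), phantom_seed = 99)
  roi <- c(4, 8, 20, 16)
  ratio <- extract_tic(c3, roi)$peak_value / extract_tic(c1, roi)$peak_value
  expect_equal(ratio, 2, tolerance = 0.05)
})
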