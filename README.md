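# ucachar

In-vitro acoustic characterization of ultrasound contrast agents (UCAs) —
microbubbles and antibubble prototypes — in R. The package implements the
full analysis chain used to compare agents:

* **Harmonic side-scatter spectroscopy** — per-pulse segmentation of
  tone-burst acquisitions, Hann-tapered averaged amplitude spectra, harmonic
  amplitude extraction, and the two nonlinear-scatter statistics
  `S_nonl(f) = 10·log10(A_CA(f)/A_sal(f))` (relative to the saline noise
  floor) and `S_nonl(f) = 10·log10(A_CA(f)/A_CA(f0))` (relative to the
  fundamental), aggregated over replicate acquisitions with per-harmonic
  Student t-tests.
* **Attenuation estimation** by the insertion-loss method,
  `α(f) = (20/d)·log10(T·A_sal/A_CA)` dB/cm, in through-transmission and
  echo-mode (reflector, doubled-path) variants, with linear-regime QC,
  sound-speed and linear-backscatter-fraction checks.
* **Contrast-specific imaging** — the three-pulse pulse-inversion +
  amplitude-modulation scheme `[1, −0.5, −0.5]` with exact linear-scatterer
  cancellation, maximum-intensity projections, linearized (squared-envelope)
  ROI time–intensity curves, and the triangular indicator-dilution model
  `C_peak = 2·dose/(Q·T_b)`.
* **Protocol arithmetic** — mechanical index ↔ peak negative pressure
  (`MI = PNP[MPa]/√f[MHz]`), dilution and number-density calculators.
* **A seeded synthetic generator** for all three record types, with known
  ground truth (harmonic ratios, attenuation coefficient, bolus kinetics)
  for every estimator.

See `vignettes/uca-acoustics.Rmd` for the methods and design rationale.

## Worked example

Characterize a strongly nonlinear agent at 2.25 MHz against a weaker
reference, all on synthetic acquisitions with known truth:

```r
library(ucachar)

# an antibubble-like agent: strong 2nd/3rd harmonics, 15 replicate injections
cfg <- sim_config(f0 = 2.25, n_cycles = 20,
                  harmonic_ratios = c("1" = 1, "2" = 0.18, "3" = 0.06),
                  noise_rms = 0.005, alpha_true = 9.7, seed = 7)

recs <- simulate_scatter_replicates(cfg)
win <- min(9, burst_duration_us(cfg))   # analysis window never exceeds the signal
tabs <- lapply(recs, function(r) {
  spec <- averaged_amplitude_spectrum(segment_pulses(r, window_us = win))
  extract_harmonics(spec, orders = c(1, 2, 3))
})
print(tabs[[1]], digits = 3)
#>   order freq amplitude snonl_fund_dB
#> 1     1 2.25     69.38          0.00
#> 2     2 4.50      8.82         -8.96
#> 3     3 6.76      3.09        -13.52
```

The first replicate scatters a second harmonic 8.96 dB below its fundamental
(on the `10·log10` amplitude-ratio scale): this replicate's lognormal
injection scatter put it below the configured mean of
`10·log10(0.18) = −7.4` dB. Averaging the 15 replicates recovers it:

```r
summarize_replicates(tabs)
#>   order   mean    sd  n
#> 1     1   0.00 0.000 15
#> 2     2  -7.62 0.762 15
#> 3     3 -12.50 0.785 15
```

Compare the second harmonic against a reference agent and estimate
attenuation from 15 simulated through-transmission pairs:

```r
h2 <- function(tt) vapply(tt, function(x) x$snonl_fund_dB[x$order == 2], 1)
compare_agents_ttest(h2(tabs), h2(tabs_ref))   # tabs_ref: same pipeline, weaker agent
#> 2nd harmonic: -7.62 vs -8.99 dB, p = 1.9e-05

pairs <- lapply(1:15, function(i)
  simulate_transmission_pair(sim_config(f0 = 2.25, n_cycles = 20,
    alpha_true = 9.7, noise_rms = 0.01, seed = 100 + i)))
attenuation_replicates(pairs, window_us = win)
#> Attenuation at 2.25 MHz: 9.700 +/- 0.003 dB/cm (n = 15)
```

The estimator recovers the configured 9.7 dB/cm to three decimals at 40 dB
SNR. Finally, a DCE-US bolus with the triangular dilution model:

```r
clip <- simulate_dceus_clip(sim_config(noise_rms = 0.01, seed = 5),
                            bolus_config(dose = 0.5), dim = c(32, 32))
extract_tic(clip, roi = c(8, 10, 24, 22))
#> TIC: 400 frames over 39.9 s; peak 0.2149 at t = 15.20 s

triangular_peak_concentration(dose = 0.5, flow = 36, duration = 20)
#> triangular model: C_peak = 0.0833 mg/mL, V_mix = 6.0 mL

mi_to_pressure(c(0.2, 0.3), 3.5, round_to = 10)
#> [1] 370 560
```

The TIC peaks within one pulsation period of the configured bolus apex
(15 s), and the protocol's MI 0.2/0.3 at 3.5 MHz correspond to 370 and
560 kPa peak negative pressure.

## Command line

A thin CLI over the same functions lives at `inst/cli/ucachar.R`:

```sh
Rscript inst/cli/ucachar.R simulate --config cfg.yaml --mode transmission --out pair
Rscript inst/cli/ucachar.R attenuation --ref pair_ref --agent pair_agent --out alpha.csv
Rscript inst/cli/ucachar.R spectrum --in pair_ref --orders 0.5,1,2,3 --out spec.csv
Rscript inst/cli/ucachar.R calibrate --mi 0.2 --f 3.5 --round 10
```

Records are stored as raw little-endian float32 samples with a JSON metadata
sidecar; configs are YAML or JSON; every run writes a JSON provenance record.

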