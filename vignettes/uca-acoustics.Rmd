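---
title: "Acoustic characterization of ultrasound contrast agents: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic characterization of ultrasound contrast agents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucachar)
```

## The measurement problem

Ultrasound contrast agents (UCAs) are suspensions of encapsulated gas
microbubbles — including antibubble variants carrying an incompressible
inclusion inside the gas phase — injected to enhance blood-pool echogenicity.
Two quantities determine an agent's imaging efficacy: the **nonlinear scatter**
it generates (the higher harmonics that contrast-specific imaging isolates
from tissue) and its **attenuation** (which limits visible depth and causes
shadowing). `ucachar` implements the in-vitro analysis chain used to measure
both, plus the dynamic contrast-enhanced (DCE-US) bolus analysis used to
compare agents under near-clinical imaging, with a synthetic acquisition
generator providing known ground truth for every estimator.

## Side-scatter spectroscopy

An acquisition is a train of 92–95 sinusoidal tone bursts (10–20 cycles at a
transmit frequency $f_0$ of 1.0, 2.25 or 3.5 MHz, 250 µs silence between
pulses) recorded at 25 MHz. The analysis:

1. **Segmentation** (`segment_pulses()`): one fixed-length window per pulse.
   The window length defaults to 9 µs — in the original protocol the duration
   of the *shortest* signal scattered by the agents, so that the window never
   extends beyond the signal. The window start is a fixed offset after each
   pulse start equal to the acoustic travel time stored in the record
   metadata: a deterministic, metadata-driven stand-in for a manual choice
   verified with needle reflections.
2. **Averaged amplitude spectrum** (`averaged_amplitude_spectrum()`): each
   segment is tapered (periodic Hann by default, reducing leakage), the DFT
   magnitude taken, and the *amplitude* (not power) spectra averaged over all
   pulses.
3. **Harmonic extraction** (`extract_harmonics()`): for each order $k$
   (0.5 marks the subharmonic) the spectral peak within
   $k f_0 \pm \Delta f$ is located; the default search half-width
   $\Delta f = f_0 / n_\mathrm{cycles}$ is half the −6 dB bandwidth of the
   transmit burst, making the search robust to sub-bin frequency offsets.
4. **Nonlinear statistics**: relative to the saline (noise-floor) spectrum,
   $S_\mathrm{nonl}(f) = 10 \log_{10} \left( A_\mathrm{CA}(f) / A_\mathrm{sal}(f) \right)$,
   and relative to the fundamental,
   $S_\mathrm{nonl}(f) = 10 \log_{10}\left( A_\mathrm{CA}(f) / A_\mathrm{CA}(f_0)\right)$,
   which mitigates the influence of bubble concentration and size. The
   $10\log_{10}$ amplitude-ratio form is the convention of the original
   analysis and is the package default; `convention = 20` selects standard
   amplitude decibels. The normalized statistic at $f_0$ is exactly 0 by
   construction.
5. **Replicates and significance** (`summarize_replicates()`,
   `compare_agents_ttest()`): mean and sample standard deviation over 15
   replicate acquisitions; agents compared per harmonic with a two-sided
   pooled-variance Student t-test at the 0.05 threshold (Welch by flag), with
   no multiple-testing correction — matching the per-harmonic testing
   protocol. Identical zero-variance groups return $p = 1$; zero-variance
   groups with different means return $p = 0$, the limit of the statistic.

### Why the default amplitude estimator interpolates

The raw maximum bin within the search band suffers Hann scalloping of up to
about 1.4 dB when a harmonic does not fall on a bin centre (e.g. 2.25 MHz
analysed in a 9 µs window). Since harmonic *ratios* are the scientific
output, the default `method = "interp"` refines the maximum bin by Grandke
two-bin interpolation and divides by the Hann main-lobe gain
$\mathrm{sinc}(\delta) / (1 - \delta^2)$ at the estimated fractional offset
$\delta$. This recovers prescribed two-tone ratios to well under 1% whenever
the analysis window does not extend beyond the tone burst. `method = "peak"`
gives the literal maximum; `method = "rss"` a band-energy amplitude that is
insensitive to line-shape distortion (relative units only).

A consequence of the window rule deserves emphasis: if the analysis window is
*longer* than the scattered burst, the burst's rectangular edge inside the
Hann taper re-introduces leakage that corrupts neighbouring harmonic
estimates by several tenths of a dB regardless of the estimator. The
package's tests therefore follow the protocol's own rule — the window never
exceeds the signal (`min(9, burst duration)` µs for synthetic records).

## Attenuation estimation

Through-transmission (insertion-loss) estimation compares the fundamental
amplitude transmitted through saline and through the agent dispersion:
$$\alpha(f) = \frac{20}{d} \log_{10} \frac{T\, A_\mathrm{sal}(f)}{A_\mathrm{CA}(f)} \quad \text{dB/cm},$$
with path length $d = 1$ cm and transmit coefficient $T$ approximated to 1
(reflection losses neglected; both are configurable in
`cuvette_geometry()`). The fundamental amplitudes are taken from the averaged
amplitude spectra, not from time-domain peaks. Echo-mode estimation
(`attenuation_echo_mode()`) applies the same formula to mean reflector gray
levels with the path doubled (forward and backward passage).

Supporting checks:

* the **linear-regime QC**: a second-harmonic/fundamental ratio above 5% in
  the agent record triggers a warning, since the insertion-loss estimate
  assumes linear bubble oscillation at the low pressures used (MI < 0.04);
* the **sound-speed check** (`sound_speed_difference()`): an arrival delay of
  0.6 µs over 1 cm against water (1480 m/s default, configurable) is an 8%
  speed-of-sound difference, bounding the error of the co-registered
  amplitude comparison;
* the **linear backscatter fraction**
  (`linear_backscatter_fraction()`): backscattered over transmitted amplitude
  in percent, with the transmit amplitude recovered from the reflector gray
  level divided by the water–aluminum reflection coefficient. The
  coefficient is computed from configurable impedances (water 1.48, aluminum
  17.3 MRayl → $r = 0.842$), since no measured value is available.

## Contrast-specific imaging and bolus analysis

The DCE-US mode transmits three pulses per frame with relative amplitudes
$[1, -\tfrac12, -\tfrac12]$ (the second and third phase-inverted and half
amplitude): a combined pulse-inversion/amplitude-modulation scheme. The
package realizes the combination as the **sum of the three RF-like signed
responses**, so any response linear in transmit amplitude cancels exactly
($1 - \tfrac12 - \tfrac12 = 0$) and the envelope is taken after summation.
Whether the original system combined RF or detected envelopes is not
documented; RF-domain summation is chosen because it is the standard
contrast-pulse-sequence realization and yields exact linear cancellation. A
pure quadratic responder $r(s) = s^2$ leaves a residual of
$(1 + \tfrac14 + \tfrac14)\,s^2 = 1.5\,s^2$, since squaring removes the sign
of the half-amplitude pulses.

Time–intensity curves are ROI means of the *squared* combined envelope —
gray levels represent signal envelopes with no log compression, so squaring
linearizes them to backscattered energy. TIC peaks are compared as percent
differences, and curves normalized to the maximum peak across agents for
joint display. Pulsatile-flow ripple is not filtered by default; an optional
moving average over one pulsation period (`smooth_tic()`) is provided.

The **triangular bolus model** uses only mass conservation and the base
duration: $C_\mathrm{peak} = 2\,\mathrm{dose}/(Q\,T_b)$ (flow in mL/s), so
$\int C\,dt = \mathrm{dose}/Q$ exactly, and the mixing volume is
$V_\mathrm{mix} = \mathrm{dose}/C_\mathrm{peak}$. An isoceles shape is *not*
assumed — the apex position is a free shape parameter of the simulator only.

## The synthetic generator

The generator emulates the structure of the study's raw recordings without
any bubble-dynamics model: harmonic content is prescribed, not emergent.

* **Scatter records**: windowed tone bursts (rectangular envelope by
  default, Gaussian optional, matching the two experimental configurations)
  with components at $k f_0$ at configured linear ratios plus an optional
  $f_0/2$ subharmonic, additive white Gaussian noise, 92–95 pulses at 25 MHz
  with 250 µs silences. Noise statistics of the real hydrophone chain are
  unknown; white Gaussian is a stand-in for a stationary floor, which is all
  the analysis assumes. Component phases are zero by default (randomizable);
  amplitude spectra are phase-blind.
* **Replicates**: per-harmonic lognormal multiplicative scatter with
  CV = 0.1 across 15 records. The protocol fixes the replicate count but not
  the injection-to-injection amplitude scatter; 10% is a typical repeatability
  for manual bolus preparation, and the lognormal keeps amplitudes positive
  while making the dB statistics approximately Gaussian — the t-test's
  assumption.
* **Transmission pairs**: the agent record scaled by
  $10^{-\alpha_\mathrm{true} d / 20}$ against an unscaled saline reference.
* **DCE-US clips**: envelope-domain images generated directly (no
  beamforming): a static speckle field linear in transmit amplitude, a
  nonlinear component $\propto a_k^2 \sqrt{\mathrm{response}(C(t))}$
  confined to a perfused band, and white noise. The square root makes the
  linearized TIC proportional to `response(concentration)` — linear in dose
  for the default identity response, as reported for low concentrations.
  The speckle fields are controlled by a separate `phantom_seed`: repeated
  boluses through one phantom share its scatterer configuration, which is
  what makes between-clip peak ratios meaningful at the few-percent level.
  Bolus defaults: 1 mL of a 0.5 mg/mL dispersion (dose 0.5 mg) into a
  36 mL/min flow, arrival 5 s, transit 20 s within a 40 s clip at 10
  frames/s, 10% pulsatility at 1 Hz emulating a peristaltic pump.

What the generator does **not** emulate: resonance behaviour and its
frequency dependence, pressure-dependent harmonic growth or bubble
destruction, buoyancy-driven drift between replicate measurements, diffraction
of the focused sources, and reverberation. Tests passing on synthetic data
therefore validate the *estimators* (segmentation, spectral arithmetic,
formula implementations, statistical aggregation), not the physics of any
particular agent.

## Numerical choices and problem sizes

* Estimator-recovery checks run at a 40 dB time-domain SNR
  (`noise_rms = 0.01` against a unit fundamental), where the attenuation
  estimator recovers $\alpha_\mathrm{true} \in \{0.3, 4.4, 9.7\}$ dB/cm with
  bias below 0.02 and SD below 0.1 dB/cm over 100 seeded pairs — the same
  ±0.1 dB/cm scale at which the physical setup was verified against corn-oil
  literature values.
* Zero-noise harmonic-ratio recovery is asserted to 0.1 dB across all three
  transmit frequencies.
* The replicate t-test's type-I error at $n = 15$ is checked against the
  binomial 99% interval around 0.05 over 10 000 null trials.
* TIC linearity uses 20 seeded clips of 24 × 24 pixels at 5 frames/s — small
  images keep the full suite fast while leaving hundreds of ROI pixels per
  frame, ample for few-percent peak precision.
* Degenerate inputs error early and explicitly: aliasing configurations,
  windows exceeding the inter-pulse spacing, empty ROIs and frame stacks,
  nonpositive reference amplitudes, and non-monotone response curves.

## Known limitations

* Harmonic amplitudes assume well-separated spectral lines; overlapping
  harmonics (very short bursts) are out of scope, as is any time–frequency
  or broadband-noise (cavitation-dose) analysis.
* The attenuation module reports $\alpha$ at the transmit frequency only —
  no attenuation spectroscopy across the burst bandwidth, and no
  shell-parameter inversion.
* The triangular model is the only perfusion model provided (no LDRW or
  lognormal transit-time fits), matching the scope of the bolus comparison
  it supports.
* Echo-mode and through-transmission estimates agree on matched synthetic
  pulses by construction; on real data, differing pulse shapes (rectangular
  vs Gaussian) introduced systematic offsets that the simulator does not
  reproduce.
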