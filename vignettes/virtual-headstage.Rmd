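---
title: "A virtual opto-electrochemical headstage: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual opto-electrochemical headstage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headstage)
```

This package is a software model of a miniaturized multisensor headstage for
monitoring cultured dopaminergic neurons: an impedance analyzer that tracks
cell proliferation on an electrode, a potentiostat for cyclic voltammetry (CV)
and constant-potential amperometry of dopamine release, and a blue-laser
stimulator for channelrhodopsin-2 (ChR2) activation. Each hardware stage is
modelled explicitly enough that its known systematics (hold images,
quantization, square-wave harmonic leakage) are reproducible, and each
measured system has a synthetic counterpart so the full chain is testable.
This vignette records the models, their assumptions, and the choices made
where the design was genuinely open.

## 1. The excitation generator

The impedance excitation is produced the way the hardware produces it: a
current DAC steps through a short sine lookup table, one table sweep per
signal period, under DMA transactions timed by a 16-bit PWM divider.

* **Table size** is 26 points. For an even table size the sample grid is
  aligned with the crest, so the table contains the exact ±amplitude codes
  (a symmetric table whose mean equals the bias level for any alignment).
* **Drive current** defaults to 31.875 µA, the lowest of the hardware's DAC
  options; through the 1 kΩ conversion resistor this is the nominal 32 mV
  excitation. The amplitude is a free parameter because the other stock
  options are not documented.
* **Clock planning.** The hardware names a fast "bus clock" and a slower
  auxiliary reference but not their frequencies; the defaults here are 24 MHz
  and 100 kHz (a typical MCU bus clock), which make the 16-bit divider limit
  bind exactly where it should — at low signal frequencies — while covering
  10 Hz–300 kHz without gaps. The integer divider quantizes the achievable
  frequency; any deviation beyond 1 % of the target is attached to the plan
  as an explicit quantization warning, never silently dropped (at 300 kHz the
  divider is 3 and the achieved frequency is ≈ 307.7 kHz).
* **Zero-order hold** is modelled rather than idealized, so the hold images at
  25× and 27× the fundamental propagate into the demodulator exactly as they
  do in hardware. An ideal sine path exists in the tests as the oracle.

Time is 0-based (sample *i* at `t0 + i/sample_rate`); potentials are mV vs
the reference electrode, currents µA unless stated.

## 2. The lock-in

Polarity-switching demodulation multiplies the ADC input by a ±1 square wave
locked to the excitation and averages over whole periods only (trailing
partial periods are discarded, mirroring the hardware's integer-period state
machine; at least 10 periods per point). For a sine `A sin(ωt+φ)` the
in-phase/quadrature means are `(2A/π)(cos φ, sin φ)`; odd harmonics *m* leak
in with weight 1/m, even harmonics cancel. The 2/π factor is the analytic
value for ±1 demodulation; since the instrument also demodulates its
internally measured excitation and reports only the channel ratio

$$ Z = r_\mathrm{ref}\,\frac{I_\mathrm{ref} + jQ_\mathrm{ref}}
                             {I_\mathrm{meas} + jQ_\mathrm{meas}}, $$

every common factor — the demodulation constant, the hold roll-off, ADC
scale errors — cancels, and no absolute calibration is needed. The phase
convention is `atan2(Im Z, Re Z)`: capacitive loads are negative.

The delta-sigma ADC is modelled as oversample → boxcar average over one hold
step → uniform 20-bit quantization over ±0.256 V (step ≈ 0.49 µV), not as a
full modulator loop. The boxcar is what the real converter's oversampling and
low-pass filtering accomplish: it attenuates the hold images (which would
otherwise be picked up by the square-wave reference's 25th/27th harmonics at
every frequency) by a factor of ~25, and its sinc droop is common to both
channels. Clipping at full scale is defined behaviour and is reported via a
clip-fraction counter. Because a low-impedance load at full drive would
saturate the ±0.256 V input (125 Ω already produces 0.32 V on the measured
channel), the model steps the drive current down — halving, at most six
times — until neither channel clips, as an operator choosing a lower DAC
current option would; the ratio calibration makes the result independent of
the drive level. Measurement noise, when requested, is additive Gaussian at
the ADC input and always seeded.

With all of this in place the full chain agrees with the closed-form Randles
impedance to well within 2 % in magnitude and ~1° in phase over
10 Hz–300 kHz, which the test suite verifies against the algebraic oracle.

## 3. The synthetic electrode and the growth study

The electrode–electrolyte interface is a constant-phase-element (CPE) Randles
cell,

$$ Z(f) = R_s + \frac{1}{1/R_{ct,\mathrm{eff}} + Q\,(j2\pi f)^\alpha},
   \qquad R_{ct,\mathrm{eff}} = \frac{R_ct}{1-\theta}, $$

with coverage θ ∈ [0, 1) representing the insulating cell layer: cells
inhibit charge transfer, so θ scales the charge-transfer resistance. This
4-parameter circuit is a modelling choice, not a measured fact; it reproduces
the qualitative growth signatures (|Z| rising, phase moving more negative)
with the fewest parameters. The default fixture values — R_s 250 Ω, R_ct
10 kΩ, Q 0.1 µS·s^0.9, α 0.9 — are chosen so that the R_ct·CPE dispersion
falls inside the 200 Hz–300 kHz averaging band of the growth statistic and
|Z| stays in a plausible kΩ range for a culture-well electrode; they carry no
measured provenance. (With the dispersion below the band edge the coverage
effect would be invisible to the band mean, which is why the corner placement
matters more than the absolute values.)

One subtlety: with a series R_s the coverage derivative of |Z| is *not*
non-negative at every frequency. Above the corner, raising R_ct,eff lowers
the real part of the parallel branch slightly faster than it moves the
imaginary part, so |Z| can dip by ~0.2 % (at 10 kHz under the defaults).
Below the corner the increase is strict and large, and the band-mean
statistic rises strictly with every step of the coverage schedule; the tests
assert exactly this corrected property.

The growth study runs the blank (θ = 0) plus one full sweep per "day" at
strictly increasing coverage — by default θ = 0.1 … 0.5 over five days, 30
log-spaced frequencies, noise off — through the complete instrument model,
and the statistic is the unweighted band mean of
`100 · |Z|_cells / |Z|_blank`. The two spectra must share a frequency grid;
there is deliberately no silent interpolation.

What the generator does *not* emulate: medium-composition drift between
measurements, electrode aging, and inter-well variability. Passing tests
therefore demonstrate the instrument model's fidelity and the statistic's
monotone response to coverage, not biological effect sizes.

## 4. The CV simulator

Cyclic voltammetry of a reversible couple is solved by explicit finite
differences on 1-D diffusion with equal diffusion coefficients for both
forms, a Nernstian surface equilibrium
`C_O(0)/C_R(0) = exp(nF(E−E⁰)/RT)` with flux balance at the electrode, and a
reflecting far wall placed six diffusion lengths out (so total material in
the grid is conserved — the suite checks 0.1 %). Only the reduced form is
present initially; the forward positive-going sweep yields the anodic peak.
Oxidation current is positive, computed from the surface gradient with a
second-order one-sided difference — the first-order gradient biases the peak
positions several mV outward at practical grids. Quasi-reversible kinetics,
adsorption, migration and convection are out of scope, as is fast-scan CV
(only its throughput arithmetic, `floor(rate × 3600 × hours)`, is provided).

Defaults: T = 298.15 K, F = 96485 C/mol, R = 8.314 J/(mol K); grid of 300
spatial points and a time step equal to 0.2 mV of potential resolution
(0.004 s at 50 mV/s), which keeps the explicit-scheme stability number
`D Δt/Δx² ≈ 0.41` below 0.5 — an unstable request errors with a suggested
step. A full ±300 mV cycle at 50 mV/s is 6,000 steps × 300 points and runs in
a fraction of a second. At these settings the one-electron separation is
57.8 mV against the ideal 57 mV (the residual is the finite switching
potential plus O(Δx) boundary error), and the two-electron case gives
28.8 mV against 28.5 mV. Peak current follows the √(scan-rate) law within a
few percent and is linear in bulk concentration.

Real voltammograms on-chip show larger separations (uncompensated resistance
in thin on-chip contacts); that distortion is deliberately not applied by
default since its magnitude is not documented.

## 5. The amperometry simulator and spike analysis

Stimulated exocytosis on a large (many-cell) electrode is modelled
phenomenologically: each stimulating event (high-K⁺ injection or light
pulse) produces one composite spike — a difference of exponentials with rise
0.2 s and decay 1.5 s, at the 100 Hz amperometry sampling rate. Consecutive
same-kind stimuli closer than 15 s form a *train*: the train's base
amplitude is drawn once (normal, mean 74.4 nA by default near the platform's
reported chemical-stimulation scale, SD 5 nA, floored at 20 % of the mean)
and the k-th pulse is scaled by `depletion_factor^(k−1)` (default 0.8),
representing vesicle-pool exhaustion. Drawing the base amplitude per train
rather than per pulse keeps within-trace peaks comparable — as single traces
show — while a between-culture SD of the reported scale (~40 nA) describes
variability across preparations, not across pulses. A low-K⁺ control
injection adds only a brief 1 %-of-mean disturbance: visible, but never a
spike. Noise is additive Gaussian (1 nA RMS default), always seeded. The
canonical protocols are three high-K⁺ injections at 115/175/235 s with a
control at 60 s, and 150 ms light pulses in trains of 1 or 5 at a 10 s
period — chosen so that successive spikes fully resolve at the default decay
time.

Analysis is Savitzky–Golay smoothing (window 11 samples, order 3 — resolves
sub-second physiology at 100 Hz; backed by `signal::sgolayfilt`, whose
boundary fits reproduce exact polynomials to the edges) followed by robust
spike detection: baseline = 10 s rolling median; threshold = 5 × robust SD
(1.4826·MAD) of the baseline-subtracted trace; one candidate per contiguous
above-threshold region; candidates must be ≥ 1 s apart and must rise at least
one threshold above the valley separating them from any taller accepted peak
(topographic prominence — without it, noise ripples riding a spike's decay
tail register as events). Amplitudes are reported baseline-subtracted at the
extremum sample, uncorrected further, and widths as full width at half
maximum. These detector parameters are package defaults, not measured
constants; analysis pipelines for such recordings rarely document their
filter settings precisely.

## 6. The optical stimulator

The driver's current-set pin integrates a PWM signal, and because of the
driver chip's internal structure *lower* duty means *higher* current; the
model is the strictly decreasing affine map with current(1) = 5 mA and
current(0) = 40 mA, a placeholder for the undocumented set-resistor transfer
curve that preserves the two documented facts (range and inverse
monotonicity). Power is zero below a 20 mA lasing threshold and linear at
1.25 mW/mA above — both fixtures fitted to the single documented operating
point (≈25 mW at 40 mA) — capped at the platform's 20 mW delivery limit.

Irradiance uses a uniform-disc beam whose diameter grows as
`d(z) = d₀ + 2z·tan(θ/2)`; the divergence is interpreted as a **full** angle
(the two conventions differ by <10 % for the geometries involved, and the
full-angle reading reproduces the documented ≈1 mW/mm² for the external
40 mW laser at 50 cm through a 50 % ND filter). Energy bookkeeping is exact:
irradiance × spot area = transmitted power. ChR2 verdicts use literature
bands — in vitro 0.3–1 mW/mm², brain tissue 1–5 mW/mm² — with "marginal"
inside the band, since threshold irradiance depends on expression level.

## 7. Interfaces, determinism and limitations

Traces serialize as `time_s,value,<unit>` CSV (the header's third token is
the unit), spectra as `frequency_hz,zmag_ohm,phase_deg`; writers emit 15
significant digits so round trips are lossless to 12. Readers validate
uniform time steps (10⁻⁶ relative), ascending frequencies and phase range,
and refuse rather than repair. YAML configs are validated block-by-block
through the same constructors as the R API (unknown keys and duplicate keys
are errors; injected defaults are reported), and every CLI run writes a JSON
manifest with command, config digest and seed. All stochastic paths take a
seed; identical (config, seed) pairs produce byte-identical outputs.

Known limitations: no DMA/PWM jitter or driver ripple; no BLE/USB transport;
no equivalent-circuit *fitting* (the synthetic direction only); no
quasi-reversible CV kinetics; no single-vesicle spike-shape analysis; no
thermal or phototoxicity modelling. The problem sizes used throughout
(30-point sweeps, 6,000-step CV grids, 300 s traces at 100 Hz) are the
package's defaults and run in seconds on one core.
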