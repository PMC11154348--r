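# headstage

A software "virtual instrument" for a miniaturized multisensor headstage used
to monitor cultured dopaminergic neurons. The package models the three
measurement modules of such a platform — a square-wave **digital lock-in
impedance analyzer** for cell-growth monitoring, a three-electrode
**potentiostat** signal chain for cyclic voltammetry and constant-potential
amperometry, and a blue-laser **optical stimulator** for channelrhodopsin-2
(ChR2) activation — together with simulators of the electrode/cell systems the
hardware measures, so that every stage of the signal chain can be exercised
and tested without hardware.

It is intended for instrumentation and biosensing developers who want a
reference model of this signal chain: what the demodulator should return for a
known load, how an ECIS-style growth statistic behaves, what an ideal
voltammogram of a reversible couple looks like, and how a spike-detection
pipeline should score a stimulation protocol.

## What is modelled

**Lock-in impedance analyzer.** A current DAC steps through a 26-point sine
table under dual-PWM timing (zero-order hold modelled explicitly), driving
31.875 µA through a 1 kΩ conversion resistor — a 32 mV excitation. The ADC
(20-bit, ±0.256 V, delta-sigma modelled as oversample → average → quantize)
has its polarity switched in step with the reference, i.e. the input is
multiplied by a ±1 square wave and averaged over ≥ 10 whole periods: for a
sine `A sin(ωt + φ)` the in-phase and quadrature means are
`(2A/π)(cos φ, sin φ)`. Both the system-under-test channel and the internally
measured excitation are demodulated and

```
Z = r_ref · (I_ref + j·Q_ref) / (I_meas + j·Q_meas)
```

so every common gain factor cancels. The growth statistic is

```
relative impedance (%) = |Z|_with_cells / |Z|_without_cells × 100
```

averaged over 200 Hz – 300 kHz. The synthetic electrode is a
constant-phase-element Randles cell `Z(f) = R_s + 1/(1/R_ct_eff + Q(j2πf)^α)`
with cell coverage θ acting on the charge-transfer path,
`R_ct_eff = R_ct/(1−θ)`.

**Potentiostat.** Cyclic voltammetry of a reversible redox couple is solved by
explicit finite differences on 1-D diffusion with a Nernstian surface
condition; at 298 K the anodic-to-cathodic peak separation approaches the
ideal `57/n` mV and the peak current follows the Randles–Ševčík `√v` law.
Constant-potential amperometry traces contain stimulus-locked exocytosis
spikes (difference-of-exponentials, ~74 nA scale) with vesicle depletion
across pulse trains; analysis is Savitzky–Golay smoothing plus robust
(median/MAD) threshold detection.

**Optical stimulator.** PWM duty → laser-diode current (inverse affine,
5–40 mA), current → power (linear above threshold, ~25 mW at 40 mA, platform
cap 20 mW), beam divergence → irradiance at the target plane, and ChR2
threshold verdicts (in vitro 0.3–1 mW/mm², brain tissue 1–5 mW/mm²).

## Worked example

```r
library(headstage)

# five days of simulated cell growth through the full instrument model
study <- generate_growth_study(seed = 42)
round(growth_band_means(study), 1)
#>  day1  day2  day3  day4  day5
#> 100.9 101.8 102.8 103.8 104.8
```

The band-mean relative impedance rises monotonically with cell coverage —
the signature of proliferation on the electrode.

```r
# one impedance point through DAC -> SUT -> ADC -> demodulation
measure_impedance_point(randles_cell(), 1000)
#> $z_mag     3523 Ohm      $phase_deg  -58.1

# reversible one-electron voltammogram at 50 mV/s
cv <- simulate_cv(redox_couple(), electrode_spec(),
                  cv_waveform_spec(-300, -300, 300, scan_rate = 50))
find_cv_peaks(cv)
#> <peak_pair> anodic 20.8 uA @ 28.6 mV; cathodic -15.47 uA @ -29.2 mV; dEp = 57.8 mV
```

57.8 mV is the simulator's rendering of the ideal 57 mV reversible
separation; a two-electron couple gives 28.8 mV.

```r
# chemical stimulation protocol: 3 high-K+ injections + 1 low-K+ control
trace <- simulate_exocytosis_trace(exocytosis_spec(), chemical_protocol(),
                                   duration = 300, seed = 42)
detect_spikes(savgol_smooth(trace))$events
#>   t_peak amplitude width_half_max
#> 1  115.7      76.9            1.5
#> 2  175.7      67.6            1.5
#> 3  235.7      72.8            1.5
```

Three spikes at the injection times, none at the 60 s control.

```r
# external stimulation laser: 40 mW, 5 mm aperture, 0.5 mrad, 50 cm, 50% ND
irradiance_at(beam_geometry(5, 0.5e-3, 500, transmission = 0.5), 40)
#> 0.92   # mW/mm^2 -> chr2_check(...) == "marginal"
required_power(1, 12.56)
#> 12.56  # mW needed to reach 1 mW/mm^2 over the 12.56 mm^2 electrode
```

A command-line front end over the same functions lives at
`inst/cli/headstage.R` (`eis-sweep`, `eis-relative`, `simulate-cv`,
`analyze-cv`, `simulate-amperometry`, `analyze-spikes`, `stimulate`), each
subcommand taking `--seed`/`--out` and writing a JSON run manifest.

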