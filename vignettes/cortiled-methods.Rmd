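---
title: "Modelling a cortical micro-LED optogenetic implant: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a cortical micro-LED optogenetic implant: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortiled` models the physics and the data analysis around a chronically
implantable 10x10 array of 40 um GaN micro-LEDs used to stimulate
opsin-expressing neurons on the mouse cortical surface. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the choices made where the underlying device characterisation
left the design open. Every empirical statement here is recomputed by the
test suite or by `scripts/acceptance.R`; nothing is quoted from data the
package cannot regenerate.

## 1. Photon transport in the device/tissue stack

### Model

A single micro-LED is a 40 um square Lambertian emitter backed by a perfect
mirror (the gold contact), radiating into a stack of plane-parallel layers:
sapphire substrate (150 um, n = 1.77), parylene-C encapsulation (7 um for
the acute configuration, 15 um for the chronic one, n = 1.64), an optional
glass cortical window (150 um, n = 1.52, acute only), then brain tissue
with the refractive index of water (n = 1.33): a 150 um white-matter layer
(mu_s = 50 mm^-1, mu_a = 0.14 mm^-1, g = 0.78) over thick grey matter
(mu_s = 11 mm^-1, mu_a = 0.07 mm^-1, g = 0.88). Device-layer indices are
standard handbook values; the device layers neither scatter nor absorb
appreciably at 450 nm over these thicknesses.

Transport is the classic weighted Monte Carlo scheme for layered media:
exponential step sampling from the total attenuation, Henyey-Greenstein
deflection, deposition of `W * mu_a/mu_t` at each interaction, unpolarised
Fresnel reflection/refraction (with total internal reflection) at every
index step, and Russian-roulette termination (threshold 1e-4, survival
probability 0.1). The random-number generator is counter-based (splitmix64
keyed on seed and photon index): runs are bit-reproducible and independent
of execution order. Conservation of the weight ledger (absorbed + escaped +
roulette residual = launched) holds to 1e-6 on every run and is asserted in
the tests.

### Three estimators, three questions

A scattering tissue is a strong diffuser (the single-scattering albedo of
white matter is 0.997), so "the light field" is not one number per voxel.
The package scores three quantities on a cylindrical (r, z) grid (10 um
voxels to 1.5 mm; z = 0 at the cortical surface):

* **Ballistic footprint** — photon weight at its *first* downward crossing
  of z = 0. This is the illuminated spot a camera focused on the surface
  would image, and is what the spot-diameter calibration uses.
* **Downward plane-crossing irradiance** (`grid$values`) — weight crossing
  each depth plane downward, per area. This emulates a stack of detector
  planes in a sequential ray tracer and is the field used for activation
  contours.
* **Collision-estimator fluence** (`grid$fluence`) — absorbed energy per
  `mu_a` per volume, the radiometric fluence rate. Exposed for users; not
  used by the calibrated metrics because diffuse build-up near the surface
  makes it ~3-5x the incident irradiance in high-albedo tissue.

All fields are normalised per 1 mW of *net* optical power delivered into
tissue (downward minus returning weight across z = 0), and every metric is
exactly linear in delivered power.

### Spot diameter: which width is "the spot"?

The spot diameter could be defined at half maximum, 1/e, or 1/e^2 of the
central footprint irradiance. Measured on 1e6-photon traces, the FWHM of
the modelled footprint is ~390/220 um (acute/chronic), the 1/e^2 diameter
~760/363 um, and the 1/e diameter ~490/270 um. The calibrated spot sizes
for this device class are 530 um (with window) and 270 um (without), so the
1/e definition is the one that matches both configurations and is the
package default; `surface_metrics()` exposes the other two. This choice is
a definition of convenience anchored to the published calibration, not a
physical claim.

### Surface irradiance and the calibration chain

The bench calibration defines cortical surface irradiance (CSI) as
delivered power over the spot-disc area, CSI = P * 4 BSF / (pi d^2 DSF)
(`csi_from_power()`). Consequently `threshold_contour()` converts a
requested CSI into a delivered power through `P = CSI * pi d^2 / 4` with
the device's spot-diameter constant (0.530 / 0.270 mm by default,
overridable), replicating how the experiments were actually scaled. With
the acute constant, 5.3 mW mm^-2 implies ~1.17 mW delivered, consistent
with the ~1.2 mW the characterisation quotes.

### A known tension in the contour metrics

Two published anchors cannot be reproduced by the same field convention:
the ~800/600 um activation widths at 150 um depth require the
net-delivered-power scaling used here (under which the matched-depth
power for the no-window scene comes out ~0.9 mW), while the published
~0.7 mW matched-depth power implies a shallower contour consistent with a
gross-influx normalisation — which in turn under-predicts the activation
widths by ~40%. The package keeps one convention (net power, downward
irradiance), documents the discrepancy, and lets the corresponding test
fail rather than switching conventions per metric.

### Multi-emitter patterns and the interposer

`superpose()` resamples the axisymmetric field onto a 3D lattice (20 um
spacing) and sums laterally shifted copies, exploiting linearity; activated
volume is a voxel count above threshold. An optional silicon interposer is
modelled as an opaque slab with a clear cylindrical via; a photon is
absorbed if it enters or leaves the slab outside the via (a thin-slab
approximation adequate at 80 um thickness). No quantitative target is
asserted for the interposer because the published geometry is ambiguous.

## 2. Axisymmetric heat diffusion

The implanted device is meshed as a 2D rotationally symmetric (r, z)
domain: parylene face on tissue, sapphire, a 5 um GaN source layer, a
polyimide carrier and encapsulating cement, with brain tissue given the
thermal properties of water. The finite-volume discretisation uses
harmonic-mean interface conductivities, backward-Euler stepping with one
Cholesky factorisation reused across steps, and Dirichlet dT = 0 at >= 5 mm.
The per-step source power is the exact interval average of the 20 Hz, 50%
duty pulse train, which keeps the discrete energy balance (injected =
stored + through-boundary) exact to solver precision; the tests assert it
to 1%.

Because the micro-LED is square and the model axisymmetric, the centre LED
becomes a volume-equivalent cylinder (radius 40/sqrt(pi) um, 5 um thick) and
off-centre LEDs become volume-equivalent concentric rings: 8 LED volumes at
the 200 um row pitch for the 3x3 pattern, 4 volumes at the half-diagonal
radius (141 um) for the 2x2 — the half-diagonal is a choice; the published
description says only "a radius similar to the distance between the rows".

Thermal power per LED is electrical minus optical power. The absolute
input-power polynomial of the real device is not published, so
`default_li_model()` assumes a 3.0 V forward voltage and a quadratic
optical-power law; absolute kelvin outputs are therefore demonstrative.
The tested surfaces are power-independent: linearity of the PDE (exact to
1e-10), the point-source Green's-function limit P/(4 pi k r) in homogeneous
water (within 5% over 0.2-1 mm on a 30 mm domain), duty-cycle averaging
against the steady solve, grid-refinement stability (<3% under halving),
and the surface-to-layer-2/3 peak ratio for the implanted 3x3 train, which
falls in [1.5, 3.0] as the published ~2 degC vs ~1 degC narrative implies.
Layer 2/3 is read at 0.20 mm depth. Blood perfusion and metabolic heat are
out of scope, which biases peak temperatures slightly upward.

## 3. Calibration module

* `fit_li()` / `invert_for_current()`: per-LED second-order polynomial of
  CSI against drive current, inverted by root finding on the fitted range
  (smallest valid root); targets beyond the curve flag the LED as having
  insufficient power, mirroring the exclusion rule used in practice.
* `ir_calibration()`: second-order polynomial of thermocouple temperature
  against infrared-camera counts.
* `accelerated_equivalent_time()`: soak-test hours mapped to equivalent
  time at 37 degC by the polymer-testing convention of rate doubling per
  10 degC, with base and interval configurable and an explicit
  `factor` override. The override exists because the published test pair
  (337 h -> 1025 h, factor 3.04) does not follow from any single stated
  bath temperature under the doubling rule; the package does not resolve
  that inconsistency.

## 4. Spike-train pipeline

Spike counts are binned at 5 ms into a 180-bin trial window: 40 bins
(200 ms) before stimulus onset, 100 bins (500 ms) of stimulus, 40 bins
after (bins are half-open, `[t, t + 5 ms)`), with an exact 5-to-1 re-bin to
the 25 ms pulse grid. Background is the mean count in the two flanking
200 ms periods scaled by 500/400 to the stimulus duration.

The time-locked criterion is one-sided: mean stimulus-window count per
trial above background mean + 2 sigma. The characterisation does not say
over what the sigma is taken; the default here is across per-trial
background counts (`sigma = "trials"`), with an across-bin variant
available. The across-trial choice is conservative — on homogeneous Poisson
nulls its false-positive rate is well below the Gaussian 2.3% tail, which
the tests verify against an independent Monte Carlo oracle.

Dose-response points are pooled across units (pooled mean = mean of unit
means; pooled SEM = sd of unit means / sqrt(n)), fitted with a logistic
whose floor is fixed at zero, and thresholded where the fit crosses
5 spikes per trial — the 50%-success reading of 10 pulses. (The equivalent
"1 spike per 50 ms" phrasing would give 10 spikes per trial; the 50%
reading is used.) The spatial profile is fitted with the weighted Gaussian
y = y0 + A exp(-(x - mu)^2 / (2 sigma^2)), weights 1/SEM^2, initial values
(0, -500, 50, 200) and box bounds ([0,2], [-900,0], [0,200], [100,1000]),
x in um relative to the probe edge (negative into the array, 200 um pitch).
Optimisation is bounded quasi-Newton (L-BFGS-B with analytic gradient) from
the stated start plus a data-driven fallback, keeping the better optimum —
pure Levenberg-Marquardt with these box bounds can stall on a bound even
from the true solution. Reported: FWHM = 2 sqrt(2 ln 2) sigma, parameter
standard errors from the weighted Jacobian scaled by reduced chi-squared
(dof = n - 4).

`preprocess_raw()` is a zero-phase 300 Hz-5.5 kHz Butterworth band-pass
followed by common-average referencing; `mua_detect()` thresholds at
-k sigma with the robust sigma = median(|x|)/0.6745. Stimulation-artefact
blanking is available as an option and off by default (artefacts were
hand-curated in the original workflow; synthetic data has none).

## 5. Behavioural scoring

Head-fixed go/no-go sessions use a 2.3 s response window (half-open at both
edges), random 1-2 s inter-trial intervals, 3-5 s no-lick periods and 5-7 s
false-alarm penalties; the association protocol presents 90% go / 10%
blank, discrimination 47.5/47.5/5% go/no-go/blank. A single lick is a
response; outcomes partition into hit / miss / correct rejection / false
alarm, with blank trials recorded but never entering the accuracy
denominator. Accuracy applies a background-lick correction: a licked trial
counts only if its in-window lick count exceeds the session background mean
by more than 2 sigma, where the background distribution is taken over
per-interval lick counts in the inter-trial gaps, normalised to the
response-window duration (the variance estimator is unstated in the source;
this is the package's choice). Freely-behaving sessions score a 1 s window
by cumulative in-beam time >= 75%, with beam intervals clipped to the
window and overlaps merged. `best_window_accuracy()` scans every block of
500 consecutive trials with a rolling sum (ties to the earliest window;
sessions may be concatenated; shorter sessions are scored whole and
flagged), and is tested against a brute-force scan.

## 6. Synthetic data: what it emulates and what it does not

The generators are pure functions of (seed, parameters) via saved-and-
restored RNG state. `gen_led_array()` draws quadratic L-I curves with
multiplicative lognormal efficiency scatter (default CV 10%) and a dead-LED
fraction. `gen_ephys()` emits inhomogeneous Poisson trains: constant
baseline (2 Hz) plus a pulse-locked component active in the ten 25 ms
on-epochs, scaled by a logistic in irradiance (ED50 2.5 mW mm^-2, slope
0.5, saturating at 12 spikes/trial) and a Gaussian in LED-probe distance
(sigma 250 um); trials cycle pseudorandomly through five irradiance levels
(1.0, 1.2, 2.8, 3.2, 4.6 mW mm^-2) and 200 um-pitch positions at one trial
per second. `gen_behavior()` draws background licks as a Poisson process,
go/no-go responses as Bernoulli with exponential latency (mean 150 ms — a
choice; latency is unpublished), and a per-session learning increment.

Two disclosed circularities bound what recovery tests show: the generator's
dose-response is logistic because the pipeline fits a logistic, and spike
locking is instantaneous. Passing recovery therefore demonstrates that the
pipeline is a consistent estimator of its own model family at realistic
counts (16 units x 50 trials/condition recovers the activation threshold
and spatial FWHM within 15%), not that cortical responses are logistic or
latency-free. Real recordings additionally contain artefacts, drift,
correlated noise and non-Poisson firing that the generator does not
emulate.

## 7. Problem sizes and numerical conventions

Default problem sizes were chosen once, as the scale at which the
statistics of interest stabilise: 1e6 photons for calibrated optical
metrics (spot-diameter MC error ~1%), 2e4-2e5 photons for structural unit
tests, the implanted thermal mesh at 5 um finest cells (~17k unknowns,
2.5 ms steps), and 16 units x 50 trials for pipeline recovery. Degenerate
inputs (empty spike tables, all-zero responses, constant camera counts,
zero-extent scenes, empty contour levels) return empty/flagged results or
errors with messages, as exercised by the tests. Seeds are explicit
arguments everywhere; no function draws from an unseeded global state.
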