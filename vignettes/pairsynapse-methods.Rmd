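---
title: "Models and methods behind pairsynapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairsynapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsynapse)
```

pairsynapse analyzes paired voltage-clamp recordings from cochlear inner
hair cells (IHCs) and the postsynaptic boutons of spiral ganglion neurons
(SGNs). Each pair probes a *single* ribbon synapse: the IHC is held near its
resting potential (−58 mV after liquid-junction correction), the bouton at
−94 mV, and every glutamate release event appears as an inward EPSC of tens
to hundreds of pA. This vignette describes the models behind each analysis
stage, the tunable parameters and their defaults, what the built-in
simulator does and does not emulate, and the numerical choices the package
makes where the underlying analysis tradition leaves them open.

Units are fixed package-wide: mV, pA, ms, and therefore fC for charge
(1 pA·ms = 1 fC), with MΩ, pF and nS for passive properties. Inward
currents are negative; EPSC amplitudes are negative pA, charges are
reported as magnitudes.

## Event detection and classification

`detect_events()` implements threshold-crossing detection:

1. slow drift is removed with a running median (window `drift_ms`, default
   20 ms — long against an EPSC, short against electrode drift);
2. the trace is smoothed with a local quadratic (Savitzky–Golay) filter of
   window `smooth_ms` (default 0.3 ms), which suppresses sampling noise
   while preserving sub-millisecond EPSC rise times;
3. the detection threshold is `threshold_mult` (default 4) times the noise
   SD of a user-designated unstimulated baseline window. The SD is
   estimated with the Gaussian-consistent MAD so that genuine events inside
   the baseline window cannot inflate the threshold — with spontaneous
   rates up to 18 events/s, a plain SD over a one-second window would be
   badly contaminated;
4. an excursion qualifies as an event if it stays below threshold for at
   least `min_width_ms` (default 0.15 ms). Correlated-noise crossings of a
   4-SD level dwell below it only briefly, while an EPSC at the detection
   limit stays below threshold for roughly its FWHM, so this single rule
   removes nearly all false positives without costing recall;
5. overlapping events are split wherever the trace re-crosses 50% of the
   threshold between peaks; excursions that never recover to half
   threshold merge into one (possibly compound) event. The onset is the
   last full-threshold crossing before the peak, linearly interpolated.

Kinetics follow the conventions of standard mini-analysis: baseline-
subtracted peak amplitude, 10–90% rise time with linear interpolation
between samples, FWHM, monoexponential decay fitted from 90% of peak to
the return to baseline, and charge integrated (trapezoid) from onset to
the return to baseline with an analytic exponential-tail correction so
that slowly decaying events are not truncated.

An event is **monophasic** when the smoothed derivative shows no
qualifying sign reversal (beyond twice the derivative noise SD) anywhere
in the event *and* the monoexponential decay fit reaches R² ≥ 0.90
(`decay_r2_min`, exposed in the interface); otherwise it is
**multiphasic**. On the decay limb, reversals are only counted once the
derivative has first turned positive, because immediately after the
smoothed peak a negative derivative is legitimate.

## Spontaneous rate and SR classes

The spontaneous rate (SR) is the number of events with onsets inside
unstimulated windows divided by the summed window duration; windows are
derived from the command epoch tables with a 50 ms settle margin after
each depolarization. A synapse is **high SR** when SR ≥ 1 event/s, low
otherwise; the boundary value 1.0 classifies as high. Distribution
summaries use the adjusted Fisher–Pearson sample skewness and CV = SD/mean
on magnitudes; histogram-style reports use 10 pA / 10 fC bins.

## Ca²⁺ current analysis

Whole-cell Ca²⁺ currents are leak-corrected with P/n calibration sweeps.
`leak_subtract()` estimates the command scale factor of the calibration
sweeps from the stored command waveforms (so both P/n and inverted −P/n
protocols work) and scales only the pulse-evoked *delta* of the
calibration current: any standing current at holding — and IHCs do carry a
standing Ca²⁺ window current at −58 mV — must not be amplified by the
scale factor. The simulator delivers its calibration pulses from a
hyperpolarized leak-holding potential (−98 mV), where Ca²⁺ channels
neither gate nor carry standing current, which is the standard
experimental design for exactly this reason.

`iv_curve()` averages the current over the 10 ms of each step (and
integrates it for the charge), `reversal_potential()` fits a line from
10 mV above the voltage of peak inward current to the strongest
depolarization and returns its zero crossing, and `fit_boltzmann()` fits

$$g(V) = \frac{g_{max}}{1 + e^{(V_{half} - V)/S}}, \qquad
  g = \frac{I_{Ca}}{V - V_{rev}}$$

to the chord conductances. Points within 5 mV of the reversal potential
are excluded (the chord conductance diverges there); initialization uses
the half-max crossing for $V_{half}$ and the 25–75% span for $S$, with
multi-start refits. The reported **threshold of Ca²⁺ influx** is the
voltage of 5% fractional activation, $V_{half} - S\ln 19$ — the analysis
tradition does not pin a numeric definition, so the 5% convention is a
documented, configurable choice. Two small biases are worth knowing
about: the line-fit reversal potential inherits a mV-scale offset from
the residual curvature of the activation curve and from the
baseline-subtracted standing current, and the 10 ms step average includes
the ~0.3 ms activation transient. Both are below the tolerances used in
the recovery tests.

## Release-intensity curve and dynamic range

Evoked EPSC charge per step, $Q_{EPSC}$, is the magnitude of the integral
of the postsynaptic current from step onset to step end plus a 2 ms tail
(events triggered at the end of a step still arrive within the synaptic
delay). The normalized release-intensity curve is fitted with

$$Q(V) = \frac{Q_{max}}{1 + e^{(Q_{50} - V)/s}}$$

on its rising limb (release tracks Ca²⁺ influx, which falls again beyond
its peak voltage). The derived quantities are exact identities of the
model: $Q_{10} = Q_{50} - s\ln 9$, $Q_{90} = Q_{50} + s\ln 9$, and the
dynamic range $Q_{90} - Q_{10} = s\ln 81$. A pair is excluded from group
statistics (`fit_ok = FALSE`) when the fit does not converge, R² < 0.5,
or the fitted midpoint falls outside the sampled voltage range — a
reproducible surrogate for the by-eye exclusion of curves a sigmoid does
not describe.

## Ca²⁺ cooperativity

The apparent Ca²⁺ cooperativity $m$ is the exponent of
$Q_{EPSC} = a \, Q_{Ca}^{\,m}$, fitted by least squares **on the raw
scale** — log-log fitting is unusable because subthreshold steps give
$Q_{EPSC} = 0$ — and unweighted. Saturation of release is handled by an
automatic plateau rule replacing by-eye truncation: with points ordered
by $Q_{Ca}$, the plateau level is the mean of the three largest
$Q_{EPSC}$ values (robust to single-point Poisson noise) and trailing
points are dropped from the first crossing of 95% of that level. For the
pooled per-class fit, each pair's $Q_{EPSC}$ is normalized by its
maximum and $Q_{Ca}$ by its value at the truncation point, so pair-scale
differences cancel and only the shared exponent remains.

## Forward masking and vesicle-pool dynamics

The forward-masking protocol depolarizes to −19 mV (the voltage of
maximal Ca²⁺ current) with a 100 ms *masker* followed after 4, 16, 64 or
256 ms by a 15 ms *probe*; maskers repeat every 20 s. The average
baseline-subtracted postsynaptic response is integrated into a cumulative
charge trace, and the first 50 ms after masker onset are fitted with

$$y_0 + A_1\left(1 - e^{-(x - x_0)/\tau}\right) + (x - x_0)\,slope .$$

Quantal conversions divide by the pair's mean sEPSC charge
$\bar{Q}_{sEPSC}$: RRP size $= A_1/\bar{Q}_{sEPSC}$ vesicles, sustained
rate $= slope/\bar{Q}_{sEPSC}$, initial rate
$= (A_1/\tau + slope)/\bar{Q}_{sEPSC}$ — the derivative of the fit at
$x_0$, which includes the sustained component; defining it as $A_1/\tau$
alone would be the other defensible reading, and the chosen definition is
recorded in the fit object. The fit onset $x_0$ is constrained to at most
5 ms after the masker so the line term cannot absorb the exponential.
Pairs with fewer than `min_events_quantal` (default 5) spontaneous events
get no quantal conversions — a mean quantal charge estimated from one or
two events is noise, and dividing by it manufactures absurd pool sizes.

Recovery is the ratio of probe to masker charge over the first 10 ms of
each stimulus, with the masker-to-masker ratio defined as 1, fitted with
$R(t) = 1 - (1 - R_0)e^{-t/\tau}$ over ISIs from 16 ms to 20 s. The 4 ms
point is excluded — about half of recorded synapses show a *lower* ratio
at 16 ms than at 4 ms, so the short-ISI point does not lie on the
recovery exponential — and $R_\infty$ is fixed at 1 because the
masker-to-masker definition builds full recovery into the curve.

## The generative simulator

`simulate_pair()` produces complete paired recordings with recorded
ground truth, under a single seed, so every stage above can be scored by
parameter recovery. Its components:

* **Quantal events.** Biexponential kernels
  $k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ with $\tau_r$ = 0.15 ms,
  $\tau_d$ = 0.55 ms, scaled to gamma-distributed amplitudes
  (mean 80 pA, CV 0.68 by default; the gamma law implies skewness
  $2\,CV$). With these defaults the mean quantal charge is ≈ 72 fC and
  the amplitude mode ≈ 43 pA, i.e. charge-histogram peaks near 40 fC. A
  fraction of events (default 0.5) is rendered multiphasic: 2–4
  sub-kernels whose consecutive gaps are drawn from U(0.4, min(0.75,
  1.5/(n−1))) ms, keeping compounds inside a 1.5 ms window while staying
  resolvable above the 0.3 ms smoothing scale.
* **Spontaneous release** is homogeneous Poisson at `sr_true` (0–18/s is
  the physiological range), scaled by pool occupancy during and after
  stimulation so that spontaneous activity resumes with a delay after
  strong depolarizations.
* **Ca²⁺ currents** are a Boltzmann conductance (defaults $g_{max}$ 5 nS,
  $V_{half}$ −30 mV, $S$ 7 mV, $V_{rev}$ +60 mV) with first-order
  activation ($\tau_{act}$ 0.3 ms), a linear leak, and Gaussian noise.
* **Evoked release** uses a partial-depletion pool model with
  release-site recruitment: a step to $V$ recruits the fraction
  $F(V) = \min\!\big(1, (\Delta drive(V)/\Delta drive(V_{ref}))^{m}\big)$
  of release sites, where $\Delta drive$ is the increment of the
  Boltzmann Ca²⁺ influx over its standing value at holding — the
  increment is what a baseline-subtracted $Q_{Ca}$ measurement sees, and
  the power law is applied to it because the cooperativity analysis
  relates *changes* of release to *changes* of Ca²⁺ influx. The
  recruited, occupied pool releases with hazard $1/\tau_{dep}$ while the
  pool refills with $\tau_{rec}$:
  $d\,occ/dt = -\max(occ - (1 - F), 0)/\tau_{dep} + (1 - occ)/\tau_{rec}$.
  The expected charge of a 10 ms step therefore scales with
  $(\Delta Q_{Ca})^m$ below saturation — the recruitment picture, in
  which stronger depolarizations open more channels and thereby activate
  more nanodomain-coupled release sites, makes the simulated apparent
  cooperativity *be* the parameter $m$ — while the release kinetics keep
  the $\tau_{dep}$ time constant that the depletion fit measures. A
  non-depleting sustained component ($F \cdot$ `sustained_rate`)
  represents resupply-fed release. The saturation reference
  $V_{ref}$ = −35 mV places release saturation well below the
  Ca²⁺-current maximum, reproducing measured release-intensity curves
  (half-activation near −47/−41 mV, saturation near −38 mV, dynamic
  ranges of 18/13 mV for the two presets). Events receive a synaptic
  delay `latency0` plus exponential jitter.
* **Presets.** `ground_truth_preset("high")` / `"low"` encode the two
  synapse classes: SR 4 vs 0.2 events/s, quanta 105 vs 62 pA, $m$ 0.8 vs
  1.4, $\tau_{dep}$ 6.3 vs 20.9 ms, latency 1.17 vs 3.34 ms with jitter
  0.38 vs 1.0 ms, RRP ≈ 14 vesicles and $\tau_{rec}$ 450 ms for both.
* **P/n sweeps** are generated inverted from −98 mV (see above), and
  passive test pulses (`simulate_testpulse()`) follow the exact
  single-RC circuit response, which makes `estimate_access()` exactly
  invertible on noiseless input.

What the simulator deliberately does **not** emulate: multi-compartment
cable filtering between bouton and pipette, AMPA-receptor desensitization
and saturation, Markov-chain channel gating (activation is first-order),
series-resistance voltage errors, and facilitation. Passing recovery
tests therefore show that the estimators are unbiased under the stated
generative assumptions — they do not certify behavior under, say, strong
receptor desensitization, which recordings made without cyclothiazide
may contain.

## Numerical choices

* All nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with
  physically bounded parameters and multi-start initialization from
  data-derived guesses; fitters flag failure instead of erroring, and
  flagged pairs are excluded from group statistics.
* `estimate_access()` fits the capacitive decay with a double exponential
  and falls back to a single exponential when the two components are not
  distinct. $R_s = \Delta V/I(0^+)$ with
  $I(0^+) = A_f + A_s + I_{ss}$; $C_m$ comes from the area under the
  fast component corrected by $((R_s + R_m)/R_m)^2$ for the steady
  current carried by the membrane — without that factor the estimate is
  biased by ~8% at bouton-like values ($R_s$ 60 MΩ, $R_m$ 1.5 GΩ), with
  it the single-RC inversion is exact.
* Charge integration is trapezoidal with interpolated window endpoints
  (second-order accurate at 20–50 kHz sampling).
* The statistical gate (`compare_groups()`) applies Shapiro–Wilk per
  group and an F test for variances at α = 0.05 and selects the unpaired
  equal-variance t test only when both pass; otherwise Mann–Whitney U.
  Tests are two-sided; no multiple-testing correction is applied, and
  summaries report mean ± sem and median with IQR.
* On-disk containers are one directory per pair: full-precision
  (17-significant-digit) CSV per sweep plus a JSON sidecar with metadata
  and, for simulated pairs, the complete ground truth. `load_pair()`
  reproduces every sample bit-exactly; a format version field guards
  against silent schema drift.

## Problem sizes used in the tests

Recovery tests run at desk scale, chosen so the whole suite stays
convenient on a laptop while every tolerance retains a comfortable noise
margin: cooperativity recovery uses 50 simulated pairs per class (single
IV runs, steps to −19 mV); forward-masking recovery uses 7 pairs of 20
masker repetitions with a 20 s spontaneous stretch each; Boltzmann
recovery uses 12 noisy IV simulations; detector scoring uses 60 s trains.
Medians over pairs are compared against the generating parameters. The
cohort pipeline test uses a deliberately small 2+3-pair cohort; realistic
cohorts (tens of pairs, full IV + forward masking) run in a few minutes
per pair.

## Known limitations

* Detection splits overlapping events only when the trace recovers to
  half threshold between peaks; how overlapping sEPSCs should count
  toward SR has no canonical answer, and at very high rates the package's
  merging rule undercounts relative to a deconvolution approach.
* The measured mean sEPSC charge is biased slightly upward by the
  detection threshold (small events are missed), which biases quantal RRP
  estimates slightly downward; at SNR typical of bouton recordings the
  bias is a few percent.
* The reversal potential from the line fit inherits a small systematic
  offset (1–3 mV) from activation-curve curvature; downstream Boltzmann
  parameters absorb it with sub-mV, sub-10% effect.
* The recovery time constant is constrained by only four ISI points, so
  single-pair estimates scatter widely; cohort medians are the meaningful
  quantity.
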