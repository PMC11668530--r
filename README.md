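# pairsynapse

Quantal and kinetic analysis of **paired recordings from single cochlear
ribbon synapses**: a presynaptic inner hair cell (IHC) under voltage clamp
and the postsynaptic bouton of a spiral ganglion neuron (SGN) recorded
simultaneously. Every glutamate release event at the single active zone
appears as an EPSC at the bouton, so these recordings resolve synaptic
transmission vesicle by vesicle. The package is written for
electrophysiologists who want a reproducible, scriptable version of the
analysis chain that is usually assembled by hand from mini-analysis
software and spreadsheets.

## What it computes

For each paired recording:

* **Spontaneous transmission** — threshold-crossing sEPSC detection
  (4 × baseline SD, robustly estimated), event kinetics (amplitude, 10–90%
  rise, τ_decay, FWHM, charge), monophasic/multiphasic waveform
  classification, spontaneous rate *SR*, and the low/high SR class
  (boundary 1 event/s).
* **Ca²⁺ channel activation** — P/n leak subtraction, IV curve, reversal
  potential, and the Boltzmann activation fit
  g(V) = g_max / (1 + exp((V_half − V)/S)) on the chord conductance
  g = I_Ca/(V − V_rev), with the voltage threshold of Ca²⁺ influx at 5%
  activation.
* **Release-intensity curve** — evoked EPSC charge per depolarization step,
  fitted with Q(V) = Q_max / (1 + exp((Q50 − V)/s)); the derived
  Q10 = Q50 − s·ln 9, Q90 = Q50 + s·ln 9 and dynamic range
  Q90 − Q10 = s·ln 81 are exact identities of the fit.
* **Apparent Ca²⁺ cooperativity** — power law Q_EPSC = a·(Q_Ca)^m fitted on
  the raw scale with automatic plateau truncation; per-pair and pooled
  (normalized) per SR class.
* **Vesicle pool dynamics (forward masking)** — eEPSC latency and jitter,
  the exponential-plus-line depletion fit
  y0 + A1(1 − exp(−(x − x0)/τ)) + (x − x0)·slope of the cumulative charge,
  quantal conversions by the pair's mean sEPSC charge (RRP size = A1/Q̄,
  initial and sustained release rates, depression ratio), and recovery from
  pool depletion across interstimulus intervals with its time constant.
* **Group statistics** — the gated two-sample rule (Shapiro–Wilk + F test at
  α 0.05 choosing unpaired t vs Mann–Whitney U) over any cohort variable,
  orchestrated by `run_pipeline()`.

A full generative simulator (`ground_truth()`, `simulate_pair()`) produces
paired recordings with recorded ground truth — Poisson spontaneous release
with gamma-distributed quanta, Boltzmann-gated Ca²⁺ currents, and evoked
release from a depleting, replenishing pool of ~14 vesicles driven through
a power-law Ca²⁺ coupling — so every estimator in the package is validated
by parameter recovery. See the methods vignette
(`vignettes/pairsynapse-methods.Rmd`) for the models and their assumptions.

## Worked example

Simulate one high-SR pair (spontaneous stretch, IV protocol with P/n
sweeps, forward masking) and run the complete per-pair analysis:

```r
library(pairsynapse)

truth <- ground_truth_preset("high", seed = 7)   # m = 0.8, RRP 14 SV, tau 6.3 ms
pair  <- simulate_pair(truth, pair_id = "demo", position = "pillar",
                       spont_ms = 10000, iv = protocol_iv(),
                       fm = protocol_fm(reps = 6))
analyze_pair(pair)
```

```
<pair_analysis 'demo'> pillar side, SR class high
  sr                   4.125
  n_sepsc              66
  mean_amp             -95.8
  mean_charge          94.81
  cv_amp               0.6793
  skew_amp             1.299
  frac_monophasic      0.5606
  mean_rise            0.4461
  mean_tau_decay       0.8241
  mean_fwhm            0.8942
  i_ca_peak            -316.1
  v_ca_peak            -15
  v_rev                58.03
  v_half               -29.69
  act_slope            6.616
  ca_threshold_v       -49.17
  q50                  -42.98
  q10                  -49.11
  q90                  -36.84
  rel_slope            2.791
  dynamic_range        12.27
  m_coop               0.836
  latency_mean         1.952
  jitter_sd            0.5355
  rrp_sv               14.22
  tau_depletion        6.822
  initial_rate         2525
  sustained_rate       440.1
  depression_ratio     5.737
  tau_recovery         806.1
  time_to_first_sepsc  196
```

Reading the output: this synapse fires 4.1 sEPSC/s (high SR) with quanta of
−96 pA / 95 fC; its Ca²⁺ channels half-activate at −29.7 mV; release
half-activates at −43 mV with a 12 mV dynamic range; the fitted apparent
Ca²⁺ cooperativity m = 0.84 indicates nanodomain-like coupling
(release controlled by roughly one channel); the masker depletes a readily
releasable pool of ~14 vesicles with τ ≈ 6.8 ms at an initial rate of
~2500 SV/s. All of these recover the generating parameters of the preset
(m 0.8, RRP 14, τ 6.3 ms, latency 1.17 + jitter) up to single-pair
sampling noise — the recovery time constant in particular is constrained
by only four interstimulus intervals per pair and scatters widely; cohort
medians are the meaningful quantity.

Cohort-level analysis, including the gated group comparisons and the
report bundle (cohort CSV, per-pair JSON, run log):

```r
report <- run_pipeline(list(
  simulate = list(n_high = 10, n_low = 21, seed = 1),
  out_dir = "cohort_out"))
report$comparisons$q10     # e.g. Q10 in high- vs low-SR synapses
```

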