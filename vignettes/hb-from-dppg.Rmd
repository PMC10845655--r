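---
title: "Hemoglobin from descending-aortic PPG: models, simulation and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemoglobin from descending-aortic PPG: models, simulation and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppghb)
```

## The measurement problem

During surgery with substantial blood loss, transfusion decisions hinge on
hemoglobin concentration (Hb), but laboratory and point-of-care measurements
are intermittent and invasive. A photoplethysmography (PPG) sensor placed in
the esophagus against the descending aorta records the transmitted/reflected
light of two wavelengths (red, ~660 nm, and infrared, ~940 nm) as voltage
traces. Each trace decomposes into a pulsatile AC component, driven by the
arterial pulse-volume change, and a quasi-constant DC component from
non-pulsatile blood and surrounding tissue. Under a first-order Beer-Lambert
expansion, the normalized pulsatile amplitude AC/DC is approximately
proportional to the concentration of the dominant absorber — hemoglobin — so
a linear model in the two wavelength ratios can track Hb continuously:

$$\widehat{Hb} = 341.84\,\frac{AC_{red}}{DC_{red}} +
  569.61\,\frac{AC_{inf}}{DC_{inf}} + 49.87 \quad [\mathrm{g/L}],$$

with both ratios as dimensionless fractions. This fixed two-wavelength
regression is shipped as `published_model()`; `fit_stepwise()` re-estimates
such models from paired data. The package's purpose is to make the entire
analysis chain around this model — waveform processing, model fitting, and
the method-comparison battery used to judge such a monitor — reproducible
and testable without access to animal recordings, which are not publicly
deposited.

### Units: fractions, not percent

AC/DC ratios are carried internally as fractions and rendered as percent
only for display. The model's own structure forces this choice: at typical
fractional ratios (~0.03) the model returns physiological Hb (~80 g/L),
whereas percent-scaled ratios would return several thousand g/L.

## The synthetic study

Because no raw data are deposited, the package generates them. The
generator is first-class, tested code, and its defaults encode the study
conditions rather than tunable knobs.

### Hemodilution-transfusion protocol (`simulate_protocol()`)

Nineteen pigs (33 ± 3.5 kg, blood volume 70 mL/kg) undergo stepwise
isovolemic hemodilution: 50 mL of blood is withdrawn per step and replaced
with fluid, with one paired (reference Hb, dPPG segment) sample per step,
until the true Hb first falls below 60 g/L; the stored blood is then
reinfused stepwise, retracing the trajectory upward. True Hb follows the
single-compartment exchange law
$Hb_{k+1} = Hb_k\,(1 - V_{ex}/BV)$.

Two defaults deserve justification:

* **`fluid_ml_per_step = 50`.** The reported protocol facts — 50-mL
  withdrawal aliquots, roughly 400-800 mL total withdrawal, a stop rule of
  Hb < 60 g/L, and roughly 16-20 paired samples per animal — are mutually
  inconsistent under a pure 50-mL exchange at 70 mL/kg (reaching the stop
  threshold would need ~18+ steps and >900 mL). During such protocols,
  maintenance crystalloid and colloid run continuously between samples; we
  model that as an additional 50 mL of isovolemic exchange per sampled
  step. With it, a default run gives ~10 dilution + ~10 transfusion steps
  per pig (~500 mL withdrawn, inside the reported range) and ~350-420 pairs
  in total, matching the study's bookkeeping.
* **Baseline Hb 90 ± 13 g/L.** Chosen from the stop threshold (60 g/L) and
  the reported average hemodilution decrease (~28 g/L). A consequence is
  that the pooled Hb mean of a protocol run (~75 g/L) sits below the
  study's pooled 83.78 g/L; the reported pooled mean, the stop rule, and the
  per-pig pair count cannot all hold simultaneously under any
  single-compartment trajectory, and we prioritise the protocol facts. The
  metric-level generator below is the one calibrated to the pooled
  marginals.

Reference measurements add Gaussian noise (default SD 2 g/L, small against
the population SD of 16.55 g/L) to the true Hb, emulating a point-of-care
blood-gas analyser; the trajectory itself wobbles by 1.5 g/L (residual SD)
around the deterministic dilution law.

### Optical model (`optical_model()`, `ratios_from_hb()`)

The generative map from Hb to ratios is affine per wavelength,
$r_\lambda = k_\lambda Hb + c_\lambda$, the first-order Beer-Lambert
linearisation. The default calibration is the *exact inverse* of the
published model: it satisfies
$341.84\,k_{red} + 569.61\,k_{inf} = 1$ and
$341.84\,c_{red} + 569.61\,c_{inf} = -49.87$
to machine precision, so noise-free generated ratios return the generating
Hb identically through `published_model()` — a round-trip identity the test
suite asserts at 1e-9 g/L. Calibrations violating the constraints are
rejected (tolerance 1e-9) unless explicitly overridden.

Within those constraints two choices remain. The Hb signal is split equally
between wavelengths ($341.84\,k_{red} = 569.61\,k_{inf} = 0.5$). The
offsets are then set (`c_red = -0.073`) so that *both ratios stay strictly
positive over the full protocol Hb range* (51-143 g/L), which waveform
synthesis requires. The alternative — pinning the red mean ratio to the
population value 3.13% at the mean Hb — forces negative ratios below about
62 g/L, i.e. exactly in the transfusion-decision region, so positivity
wins; the channel mean ratios are consequently implied by the calibration
(~4.95% red, ~2.98% infrared at 83.78 g/L) rather than pinned. A related
structural fact is worth stating plainly: under the exact-inverse
constraint the 92 g/L protocol range maps to a total ratio span wider than
the population min-max span of either ratio, whatever the slope split. The
published coefficients are regression estimates from noisy, correlated
predictors, not a deterministic transfer function, and no affine inverse
can reproduce both them and the marginal ranges. The two generators divide
the labour:

* `ratios_from_hb()` / the waveform path: exact-inverse physics, positive
  ratios, used for round-trip validation of the signal chain.
* `metric_dataset()`: draws the two ratios from a bivariate normal with the
  population marginals (3.13% ± 1.35%, 3.73% ± 1.45% as fractions,
  correlation 0.7 — the inter-ratio correlation is not reported anywhere
  and 0.7 is a free parameter) and generates Hb *from the published model
  plus residual noise*. Its ground truth is therefore the published
  coefficient vector itself, which makes it the right generator for
  coefficient-recovery and agreement experiments. The default residual SD
  9.7 g/L is calibrated from the reported model-reference correlation:
  $16.55\sqrt{1 - 0.81^2} \approx 9.7$.

Evaluating the published model at the population mean ratios gives
~81.8 g/L, not the pooled mean Hb of 83.78 g/L; this ~2 g/L internal
inconsistency of the reported values propagates to the metric generator
(its Hb mean is ~81.8) and is left as is — recalibrating it away would
silently change the published coefficients' status as ground truth.

### Waveforms (`waveform_synthesize()`)

Each channel is built as
$DC\,(1 + r\,p(t)) + \text{wander} + \text{artifacts} + \text{noise}$,
where $p(t)$ is a zero-mean periodic beat template with unit peak-to-trough,
so the pulsatile peak-to-trough is exactly $r \cdot DC$ by construction. The
template is a sum of two Gaussians — a systolic peak and a delayed, smaller
bump — the simplest shape producing the slight dicrotic notch by which
descending-aortic PPG is identified. Respiratory wander is a <0.5 Hz
sinusoid (default 0.25 Hz at 1% of DC), peristalsis transients are optional
smooth bumps, and the trace is quantised to the recorder's 16-bit range
(0-20 V at 500 Hz). The DC level of the infrared channel is calibrated to
the reported mean/SD only: the reported min-max of that row is internally
inconsistent (max < mean, evidently a typo).

What the generator does *not* emulate: hemodynamic feedback (cardiac
output or pressure responses to bleeding), oxygen-saturation effects on
absorption (the study ventilated with 100% oxygen precisely to mute them),
background light contamination of DC from esophageal tissue, or sensor
repositioning. Passing round-trip tests therefore show that the *signal
chain* is faithful, not that real esophageal recordings would be this
clean; on real data the stability selector and signal-loss flags do the
work that clean simulation makes trivial.

## Signal processing

`extract_metrics()` implements the per-segment chain:

1. **FIR bandpass** (`bandpass_filter()`): linear-phase Hamming-window
   design, applied with group-delay compensation, tap sum re-centred so the
   DC gain is exactly zero. Default band 0.5-10 Hz: heart rates of 56-159
   bpm put the cardiac fundamental at 0.93-2.65 Hz, so 10 Hz keeps at least
   three harmonics while 0.5 Hz rejects respiration and peristalsis. A
   20th-order FIR cannot realise this band at 500 Hz (its transition width
   is tens of Hz); the default order 2500 attains, by measured response,
   DC rejection below 1e-3, >97% attenuation at 0.2 Hz and <1% passband
   ripple. The first and last `order/2` samples are start-up edges,
   excluded from beat selection.
2. **Beat detection** (`detect_beats()`): systolic peaks as local maxima
   with a minimum spacing of one minimum beat period (60/`hr_max`), onsets
   at the troughs between peaks; beats are half-open index intervals.
3. **Stable-run selection** (`select_stable_run()`): among all windows of
   nine consecutive beats, the one minimising the summed CV of period and
   amplitude, subject to both CVs ≤ 10% (the source protocol says only
   "stable"; CV thresholds are the configurable operationalisation).
   No qualifying window ⇒ the segment is flagged as signal loss and its
   metrics propagate as `NA`, never dropped silently.
4. **Metrics**: per selected beat, AC is the peak-to-trough of the filtered
   pulsatile signal (the most common PPG convention; RMS or harmonic
   amplitudes would differ by a shape factor), DC is the mean of the *raw*
   signal over the beat — the bandpass removes DC by definition, so DC must
   come from the unfiltered trace. No ambient-light subtraction is applied
   (whether the original DC included one is unstated). The six metrics are
   means over the nine beats; ratios are formed from the averaged AC and DC.

On noise-free synthetic waveforms the extracted ratios match the generating
ratios to well within 1% (filter ripple); with default noise and wander,
within 2% across the heart-rate range.

## Model fitting

`fit_stepwise()` is forward stepwise OLS with backward removal at
SPSS-style thresholds (enter at p < 0.05, remove at p > 0.10), the
procedure's standard defaults, both configurable. Two deliberate fidelity
choices: all pairs are pooled across animals in one regression (ignoring
within-pig correlation, exactly as the original analysis did), and there is
no regularisation or cross-validation — the original model was never
validated on a new animal, and the package replicates the procedure, not an
improved one. On near-collinear predictors (as protocol-generated ratios
are) stepwise may legitimately retain a single ratio whose coefficient
absorbs both; tests assert prediction quality, not a fixed predictor set,
in that regime.

## The evaluation battery

* **Correlation**: product-moment r with the two-sided t-test p.
* **ROC at the transfusion triggers**: positives are reference Hb < 60 g/L
  (scores low ⇒ positive) or > 100 g/L (scores high ⇒ positive). AUC is
  trapezoidal (= Mann-Whitney with ties counting half; the test suite
  checks it against brute-force pair counting), the CI is DeLong by
  default with a bootstrap alternative, and the cut-off maximises the
  Youden index with ties resolved toward higher sensitivity.
* **Bland-Altman with repeated measures** (`bland_altman_rm()`): bias is
  the mean difference; the SD of differences comes from one-way variance
  components of the differences on subject (between + within), the
  multiple-measurements correction that keeps heavily sampled animals from
  dominating. A naive pooled mode is available for comparison; a single
  subject falls back to it with a warning. LOA are bias ± 1.96 SD;
  percentage error is 100·1.96·SD / mean(reference) — the reference-method
  mean, consistent with the reported 33% ≈ 1.96·14.13/83.78.
* **Polar trending** (`polar_trend()`): consecutive within-subject change
  pairs map to an angle relative to the identity direction,
  $45° - \operatorname{atan2}(\Delta_{test}, \Delta_{ref})$ folded into
  (-90°, 90°], and a radius equal to the mean of the two changes.
  Concordance is the share of non-excluded points within ±30°. The
  exclusion radius defaults to 2 g/L — the reference analyser's noise
  scale — because per-step protocol changes are only ~3 g/L; a zone of
  10 g/L (a common choice for this plot in cardiac-output trending) would
  exclude essentially every point of such a protocol and leave the rate
  undefined. The radius is configurable and echoed in every report.
* **Error grid** (`error_grid()`): decision bands L (< 60 g/L: transfuse),
  M (60-100: judgement), H (> 100: no transfusion); Zone A = same band,
  Zone C = opposite extremes, Zone B = other disagreements. This band
  encoding approximates the published three-zone polygon grid by its
  decision thresholds; the exact polygon coordinates live in the original
  error-grid reference and are not reproduced here — the approximation is
  flagged in the function documentation and visible in the plot.
* **LOA sample size** (`loa_sample_size()`): $se_{LOA} = \sqrt{3 s^2/n}$,
  95% CI half-width $1.96\,se_{LOA}$. At s = 20 g/L and n = 300 this gives
  a half-width of 0.196·s; the value "about 0.22·s" sometimes quoted for
  this design is not reproduced by the formula and the discrepancy is
  documented rather than reconciled.

All statistics are invariant to row order; polar angles negate and zones
are preserved under method swap; these are property-tested.

## Numerical and design notes

* Determinism: every generator takes a `seed`; identical (config, seed)
  gives bit-identical outputs, including written waveform files. Seeds are
  used through a restore-after-use wrapper, so generators do not perturb
  the caller's RNG stream.
* Indices are 1-based with half-open beat intervals `[onset, end)`,
  documented at the type level.
* Degenerate inputs are first-class: zero-variance correlations report
  `NA`, single-class ROC is rejected, all-excluded polar sets report an
  undefined rate, empty hemodilution runs (baseline already below the stop
  threshold) are flagged, pure-noise segments flow through as signal loss.
* Desk-scale problem sizes: default test and example runs use 1-4 pigs,
  12-20 s segments, and 60-500 replicate draws; the full 19-pig
  metric-level replication runs in seconds, and the waveform path costs
  about a second per pig at 15-s segments. All sizes scale up by config.

## Known limitations

* The optical model is affine and noise is Gaussian; saturation,
  wavelength-dependent scattering, and fluid-type effects on absorption are
  out of scope.
* The metric-level and waveform-level generators are calibrated to
  different anchors (population marginals vs. exact-inverse physics);
  agreement statistics from the waveform path are optimistic relative to
  the reported ones because the true optical residual of the original study
  (sensor coupling, background light) is unknown and not modelled.
* The error grid is a band approximation, not the original polygons.
* ROC confidence intervals assume independent observations; with ~20
  repeated measures per animal they are anti-conservative, exactly as in
  the original analysis.
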