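---
title: "Methods: pillar-based EHT contractility and calcium-transient kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pillar-based EHT contractility and calcium-transient kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarbeat)
```

pillarbeat quantifies two readouts of engineered heart tissue (EHT)
physiology: contractile force, measured optically from the bending of the
elastic pillars the tissue is suspended between, and intracellular calcium
handling, measured from paced fluorescence-indicator traces. This vignette
is the package's own account of the models, the estimators, and the design
choices behind them — including the places where a convention had to be
fixed because the underlying measurement practice leaves it open.

## 1. The force transducer: a cantilever pillar

A contracting EHT pulls the heads of its two supporting PDMS pillars toward
the tissue midline. Each pillar is modelled as a cantilever beam with a
concentrated load $P$ at the free end:

$$\delta = \frac{P L^3}{3 E I}, \qquad I = \frac{\pi d^4}{64},$$

with $L$ the pillar length, $E$ the Young's modulus of the PDMS, $d$ the
pillar diameter, and $I$ the area moment of inertia of the circular
cross-section. The package default geometry is $L = 12$ mm, $E = 1.7$ MPa,
$d = 1.2$ mm, which gives a bending stiffness

$$k = \frac{3EI}{L^3} \approx 0.300\ \mathrm{N/m},$$

i.e. 1 µm of head deflection per ~0.30 µN of tip force. Force is therefore
read out as $P(t) = k\,\delta(t)$, with displacement as the only measured
variable.

Assumptions and their consequences:

* **Small deflections.** The linear formula ignores geometric
  nonlinearity. `displacement_to_force()` warns when $\delta$ exceeds 10%
  of $L$ (1.2 mm, i.e. ~360 µN) — far above physiological EHT forces, so
  the warning marks data errors rather than a modelling regime.
* **One pillar.** Force is reported for the tracked pillar only. The
  formula concerns a single cantilever; no doubling for the two-pillar
  construct is applied.
* **Baseline policy.** Whether reported force should be measured from the
  relaxed (diastolic) pillar position or from the reference frame of the
  recording is a convention. The package computes both: `force_n` is
  relative to the diastolic baseline (median of the lowest decile of the
  displacement trace — robust to a few percent of outlier frames), and
  `force_raw_n` keeps the absolute deflection. The baseline-subtracted
  value is the headline metric.

## 2. Subpixel motion tracking by phase-only correlation

Pillar-head displacement between frames is fractions of a pixel to tens of
pixels at the platform's 3.79 µm/pixel scale, so the tracker must resolve
well below one pixel. `poc_shift()` implements phase-only correlation
(POC): for frames $f$ and $g$ with spectra $F$ and $G$, the normalised
cross-phase spectrum

$$R = \frac{G\,\overline{F}}{\lvert G\,\overline{F}\rvert}$$

discards all magnitude information. For a pure translation the inverse
transform of $R$ is a single sharp kernel centred at the true shift, and
because the magnitude is normalised away the estimate is exactly invariant
to positive intensity scaling — the property that makes the method robust
to illumination and brightness drift between frames.

Numerical choices, each of which matters at the 0.01-px level:

* **Apodisation.** Both frames are multiplied by a Hann window before the
  FFT. Without it, wrap-around discontinuities at the frame edges leak
  phase error into every bin. The window breaks exact circular-shift
  equivariance, which costs ~0.02 px on synthetic circular shifts — a good
  trade against the much larger edge artefacts on real (non-periodic)
  frames. `window = FALSE` is available for strictly periodic inputs.
* **Spectral weighting.** The cross-phase spectrum is weighted by an
  isotropic Gaussian ($\sigma$ = 0.15 cycles/pixel by default) with the DC
  bin removed. Once noise dominates a frequency band, its phase is
  uniformly random and only dilutes the correlation peak; down-weighting
  high frequencies is what keeps the estimator at ~0.05 px under 5%-of-range
  noise instead of ~0.4 px without weighting. The DC removal also makes
  additive offsets irrelevant.
* **Subpixel refinement.** The correlation surface of POC has a known
  analytic form (a 2-D Dirichlet/periodic-sinc kernel). The implementation
  first solves the closed-form three-point fit of that model along each
  axis (with a parabolic fallback when the configuration is degenerate),
  then refines by maximising the *continuous* band-limited correlation
  surface — the trigonometric polynomial defined by the weighted cross-phase
  spectrum — with L-BFGS-B inside the ±1-px cell of the integer peak. This
  is the same analytic peak model, fitted against every spectral bin rather
  than a 3×3 neighbourhood.
* **Phase floor.** Bins whose cross-power magnitude is below
  $10^{-15}$ of the maximum have no defined phase and are zeroed rather
  than divided.
* **Confidence.** The correlation peak value is normalised so identical
  frames give exactly 1. Pairs whose peak falls below `peak_floor`
  (default 0.3) are flagged low-confidence; `track_stack()` aborts when
  more than 20% of pairs are flagged, and otherwise propagates the flags.
* **Degenerate input.** A constant frame has no phase information;
  registration is refused ("ill-posed") rather than returning an arbitrary
  zero.

`track_stack()` chains per-pair estimates over the recording. The default
mode is frame-to-frame (`"cumulative"`): inter-frame deformation during an
EHT twitch is small, so each registration stays deep inside its search
basin; the cost is slow random-walk accumulation of per-pair error. The
`"fixed_reference"` mode registers every frame against the first —
accumulation-free, at the price of large excursions within the window.
Whether the original instrument scripts re-anchored their reference is not
something a trace file records; both modes are provided and agree to
~0.005 px on noiseless rigid motion.

The 2-D shifts are reduced to the 1-D pillar deflection by projection onto
a displacement axis. If the axis is not supplied in the config it is
estimated as the first principal component of the shift cloud, with its
sign fixed so that the dominant transient excursions — contractions — are
positive. This encodes the convention "positive displacement = head moving
toward the tissue midline" without requiring knowledge of the scene
geometry.

An exhaustive normalised-cross-correlation estimator
(`brute_force_shift()`: integer search followed by continuous refinement of
the resampled correlation) is part of the package as the independent oracle
used throughout validation; it shares no code path with the phase-based
estimator beyond the resampling primitive.

## 3. The synthetic-video generator

`simulate_pillar_video()` renders what the tracker actually sees: a
high-contrast textured disk (the pillar head) on a darker background,
rigidly translated frame by frame by $\delta(t) = P(t)/k$ — the same beam
compliance the analysis inverts, so ground truth and analysis cannot drift
apart. Design decisions:

* **Sub-pixel rendering.** Translation is applied in the Fourier domain
  (band-limited resampling), because a tracker claiming subpixel accuracy
  must be tested against faithfully rendered non-integer shifts, not
  integer-pixel approximations. The scene is band-limited (Gaussian
  spectral envelope, texture cutoff 0.35 cycles/px, composite cutoff 0.4)
  so the periodic resampling is ringing-free.
* **Texture.** The head texture is a seeded smooth random field: a
  well-conditioned phase spectrum by construction, and fully reproducible.
  A flat texture is rejected — registration on it would be ill-posed.
* **Force waveform.** Each pacing period contains a $\sin^2$ twitch
  (default width 0.4 s at 1 Hz pacing) reaching the prescribed per-beat
  peak force; defaults emulate 1 Hz field stimulation recorded at 30
  frames/s and 3.79 µm/pixel.
* **Nuisance processes.** Multiplicative per-frame brightness drift
  (exercising the brightness-invariance claim) and additive Gaussian noise
  are applied after translation, in that order.
* **What is not modelled.** No optics (PSF, vignetting), no tissue
  deformation, no rotation — the generator produces rigid translation
  only, which is the regime the cantilever readout assumes. Passing the
  recovery tests therefore validates the estimation chain, not the rigidity
  assumption itself on real tissue.

Frame rate is deliberately *required* in configs for real recordings: TIFF
containers carry no timing metadata and a silent default would corrupt
every kinetic quantity downstream.

## 4. Calcium transients: trace model and feature definitions

`simulate_calcium_trace()` builds paced indicator traces as
baseline + transient train + linear drift + Gaussian noise. Each transient
rises from the stimulus as a raised cosine over `rise_time_s` and then
decays as a single exponential with rate `decay_rate`. The defaults —
1 Hz pacing sampled at 100 Hz, rise 0.15 s, decay rate 7 s⁻¹ (80% decay in
0.23 s), amplitude equal to baseline (ΔF/F₀ = 1), noise 5% of amplitude,
bleaching drift −0.5 intensity/s — describe a briskly responding
field-stimulated cardiomyocyte preparation with a modern red indicator;
they were chosen once as typical of such recordings and double as the
package's standard validation conditions.

The analysis reports three per-beat features:

* **amplitude** — peak ΔF/F₀ above the beat's pre-onset baseline;
* **time to peak** — upstroke onset to peak;
* **decay80** — time from the peak until the signal has fallen by 80% of
  its amplitude (20% remaining), the "decay tau" convention of
  high-throughput transient screens. For a clean exponential with rate
  $\lambda$ this equals $\ln(5)/\lambda$, which is the closed-form anchor
  used in validation. A true exponential-fit time constant is available as
  a clearly separate secondary output (`exp_tau = TRUE`), because "tau"
  suggests an exponential constant while the operational definition above
  is a fixed-fraction decay time; the two differ whenever the decay is not
  mono-exponential.

Conventions that had to be fixed:

* **Time origin.** Stimulus timestamps are not part of a trace file, so
  time-to-peak is measured from the detected upstroke onset: the 10%
  amplitude crossing, linearly interpolated between samples. The
  generator's ground truth records the analytic onset→peak interval for
  its waveform ($r\,(1 - \arccos(0.8)/\pi)$ for a raised-cosine rise of
  duration $r$) alongside the stimulus→peak rise time, so recovery is
  well-posed under the convention the estimator can actually realise.
* **Amplitude reference under drift.** With additive drift the "baseline"
  is time-varying, and any constant-$F_0$ normalisation measures amplitude
  against the mid-recording baseline. Ground truth therefore defines the
  per-beat ΔF/F₀ amplitude against the instantaneous baseline
  $B(t) = \mathrm{baseline} + \mathrm{drift}\cdot t$. This is bookkeeping,
  not estimation: mislabelling the truth as amplitude/baseline(0) shows up
  as a spurious "bias" exactly equal to the drift accumulated over half the
  recording.
* **Incomplete relaxation.** At 1 Hz pacing a slow decay
  ($\lambda \lesssim 4$ s⁻¹) has not returned to baseline by the next
  stimulus. The operational features then genuinely differ from the
  single-transient closed forms: the working baseline is elevated and the
  fixed-fraction decay time shortens. The closed-form checks are therefore
  run at pacing slow enough for full relaxation; the 1 Hz defaults relax to
  <0.3% residual. This is a property of the measurement definition, shared
  with any fixed-fraction decay analysis, and worth remembering when
  comparing slow-decay groups across pacing protocols.

## 5. Estimator design: unbiasedness under noise

The obvious estimators for these features are biased at exactly the noise
level of interest, and the package's implementations were chosen to remove
those biases rather than average over them:

* **$F_0$ estimation.** A raw low percentile of a noisy trace is biased
  low by order one noise SD (it selects noise minima), which inflates every
  ΔF/F₀ amplitude — +6% at the standard 5% noise. `normalize_dff()`
  instead *classifies* the baseline region on a smoothed copy (samples
  below the 10th percentile of the 50-ms moving average) and averages the
  raw values there. Inside `transient_features()` the baseline is refined
  further: the pooled pre-onset diastolic windows (0.15–0.05 pacing periods
  before each onset) are *phase*-selected, hence statistically independent
  of the per-sample noise, giving an unbiased $F_0$ and an unbiased linear
  drift estimate from the same samples. A quantile-selected drift fit was
  measured +3% biased through noise-correlated sample selection; the
  diastolic-window fit removes this entirely.
* **Peak amplitude.** Reading each beat's maximum sample under noise is a
  max-statistic, biased high by ~1–2 noise SDs (+6–9% at standard
  conditions). Instead, the peak location is estimated *once per ROI* from
  the ensemble-averaged beat (parabola-refined argmax of the mean aligned
  waveform), and each beat's amplitude is read by quadratic interpolation
  of its raw samples at that fixed phase. An estimator that is linear in
  the data at a noise-independent location has no selection bias by
  construction; calibration at the standard conditions measured ≤1.4% bias
  and ~2.7% RMSE after 10-beat averaging.
* **Time to peak** uses the per-beat raw argmax relative to the
  interpolated onset. Its discretisation error averages out over random
  stimulus phase; measured bias ≤1.3% noiseless, ≤0.8% under noise.
* **decay80** is the first crossing of `peak − 0.8·amplitude` on a 25-ms
  moving average, linearly interpolated. The light smoothing suppresses the
  first-passage bias (a noisy trace crosses any downward threshold early;
  unsmoothed this costs −7%) while adding only ~+1% systematic delay on the
  standard kinetics; the two effects were balanced at the default window.
* **Beat segmentation** is peak-anchored: candidate peaks (local maxima of
  a heavily smoothed copy above the half-amplitude level, thinned by a
  0.6-period refractory rule) are detected first, and the onset is found by
  walking back from each peak to the 10% crossing. Threshold-first
  segmentation mis-anchors entire recordings when noise re-crosses the
  onset level during the decay; peak-first anchoring is immune. Partial
  first/last windows are discarded (a window needs a 5%-of-period pre-onset
  margin and a full period of data).
* **Invalid beats** (no decay crossing within the window, non-positive
  amplitude) keep their row with `valid = FALSE` and `NA` features —
  never fabricated values — and `aggregate_roi()` averages only valid
  beats, recording how many (target 10, the usual waves-per-ROI
  convention).

## 6. Two-group statistics

`compare_groups()` wraps the unpaired two-tailed t test (pooled-variance
"Student's" form by default, to match the naming conventions of the
studies this pipeline serves; the Welch variant is a flag away and is the
better default when variances may differ). Results carry the reporting
conventions of the field: mean ± SEM per group and the box summary
(median, quartiles, min, max). Degenerate input — zero variance in both
groups — returns $t = 0$, $p = 1$ (equal means) or $p = 0$ (different
means) with an explicit flag instead of an error. No multiplicity
correction is applied by default (per-feature tests are conventionally
reported unadjusted); `compare_features(p_adjust = "holm")` provides the
adjusted variant. Significance stars are cosmetic output only; numeric p
values are always emitted.

The simulation harness (`simulate_force_samples()`) draws per-tissue true
forces as Gaussians with a 15% between-tissue coefficient of variation and
adds a 2% measurement error, consistent with the end-to-end tracking
accuracy demonstrated by the validation suite. The 15% CV is the
package's standing assumption for replicate EHTs from a single
differentiation batch — tight but realistic for mature protocols, and the
regime in which a 50% force reduction is detectable at n = 5 tissues per
group with power above 0.9 (the design the statistical validation
mirrors). With a larger CV the same effect needs more tissues; the harness
makes that trade-off directly computable.

## 7. Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) runs at
sizes chosen to estimate each quantity stably: 50 seeded 96×96 frame pairs
with shifts in [−5, 5] px for registration accuracy (noiseless, 5%-noise,
and oracle agreement); 20 seeded 60-frame videos at 10–40 µN for
end-to-end force recovery (noiseless and noisy); the λ ∈ {2, 4, 8, 16} s⁻¹
closed-form decay grid; 100 seeded ROIs at the standard noisy conditions
for feature bias/RMSE; 2000 null and 500 alternative cohort simulations
for type-I error and power. On one CPU the full suite runs in about two
minutes and the acceptance script in about one.

## 8. Known limitations

* The generator's videos contain rigid translation only; real recordings
  include tissue deformation, focus drift and illumination structure the
  tests do not exercise. Passing validation demonstrates the estimation
  chain, not robustness to every imaging pathology.
* Cumulative tracking accumulates a random walk of per-pair errors; for
  recordings much longer than a few hundred frames, fixed-reference mode
  or periodic re-anchoring is preferable.
* The operational decay80 depends on the pacing window when relaxation is
  incomplete (section 4); cross-study comparisons of slow decays should fix
  the pacing protocol.
* The beam model treats the pillar as linearly elastic with known $E$; no
  calibration of $E$ from reference loads is provided.
* Amplitude in ΔF/F₀ units presumes the indicator responds linearly over
  the measured range; no dye calibration to absolute calcium concentration
  is attempted.
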