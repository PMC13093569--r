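# pillarbeat

Contractile-force and calcium-transient analysis for pillar-based
engineered heart tissue (EHT).

EHTs — strips of cardiomyocytes in a hydrogel suspended between two
elastic PDMS pillars — report their contractile force mechanically: each
twitch bends the pillars, and the bending is visible in an ordinary
microscope video. pillarbeat turns those videos, and the paced
fluorescence traces of a calcium-imaging experiment, into the quantities a
contractility study reports, with a synthetic-data generator that makes
every stage of the pipeline verifiable against exact ground truth. It is
aimed at labs running pillar-based EHT assays (disease modelling, gene
rescue, drug testing) and at anyone who needs a tested, scriptable
replacement for one-off tracking and trace-analysis scripts.

## What it computes

**Force.** Each pillar is a cantilever beam with a concentrated end load:

    delta = P * L^3 / (3 E I),   I = pi * d^4 / 64

so force is deflection times the bending stiffness `k = 3EI/L^3`. With the
default geometry (L = 12 mm, E = 1.7 MPa, d = 1.2 mm), `k ≈ 0.300 N/m` —
about 0.30 µN per micrometre of head deflection. Pillar-head motion is
tracked to subpixel precision by **phase-only correlation** (POC):
registration on the phase of the cross-power spectrum, which is invariant
to brightness changes and localises translations to a few hundredths of a
pixel at the platform's 3.79 µm/pixel scale. Displacement is projected
onto the contraction axis, converted to force, and summarised per beat
(per-beat peaks, their mean, and the force at maximum pillar deflection).

**Calcium.** Paced indicator traces are normalised to ΔF/F₀, segmented
into beats, and reduced to per-beat **amplitude**, **time to peak**, and
**decay80** — the time for an 80% reduction from the peak (equal to
ln(5)/λ for an exponential decay with rate λ) — then averaged over ~10
beats per region of interest.

**Statistics.** Two-group comparisons with unpaired two-tailed Student's
t tests (Welch variant behind a flag), mean ± SEM, and box summaries
(median, quartiles, min, max), plus a simulation harness for type-I error
and power at realistic between-tissue variability.

**Synthetic data.** `simulate_pillar_video()` renders a textured pillar
head rigidly translated by the beam deflection of a prescribed force
waveform (band-limited subpixel rendering, brightness drift, noise);
`simulate_calcium_trace()` builds paced transient trains with known
kinetics. Both return exact ground truth alongside the recording.

## Worked example

Simulate a 3-second recording of an EHT beating at 1 Hz with 25 µN peak
force, then recover the force from the video alone:

```r
library(pillarbeat)

sim     <- simulate_pillar_video(peak_force_n = 25e-6, n_frames = 90)
disp    <- track_stack(sim$video)              # POC subpixel tracking
force   <- displacement_to_force(disp)         # cantilever model, k ~ 0.300 N/m
metrics <- beat_metrics(force, pacing_rate_hz = 1)
metrics
#> <beat_metrics> 3 beats: mean peak 24.94 uN, max 24.94 uN
```

The tracker recovers the prescribed 25 µN to 0.2% from pixel data alone
(the residual is twitch-peak sampling at 30 frames/s). `autoplot(disp)`
and `autoplot(force, metrics)` draw the traces.

Calcium kinetics from a noisy paced trace (5% noise, bleaching drift):

```r
ca    <- simulate_calcium_trace(seed = 42)     # 1 Hz pacing, 13 s
feats <- transient_features(ca$trace)
aggregate_roi(feats)
#> # A tibble: 1 × 5
#>   roi_id n_beats amplitude time_to_peak_s decay80_s
#>   <chr>    <int>     <dbl>          <dbl>     <dbl>
#> 1 roi1        10      1.02          0.120     0.229
```

against generating values of 1.0 (ΔF/F₀), 0.119 s (onset to peak) and
0.230 s (ln(5)/7). Two-group comparison on a simulated five-tissue cohort
with a prescribed 50% force reduction:

```r
d <- simulate_force_samples(n_per_group = 5, seed = 7)
compare_groups(d, force_n, group)
#> <group_comparison> Student (pooled) t test
#>   control    n = 5, mean 2.926e-05 +/- 2.62e-06 (SEM)
#>   disease    n = 5, mean 1.841e-05 +/- 1.07e-06 (SEM)
#>   t = 3.838, df = 8, p = 0.004964 **
```

`tidy()` and `glance()` return these results as tibbles;
`autoplot()` draws the box-and-whisker comparison. For file-based runs,
`run_force_pipeline()` / `run_calcium_pipeline()` take a strict YAML
config (see `run_config()`) and write displacement/force/feature CSVs,
metrics JSON and a run log; `run_demo_cohort()` executes the whole
two-group study end to end on synthetic data. The same pipelines are
reachable from a shell via `inst/scripts/pillarbeat-cli.R`
(`simulate`, `track`, `force`, `calcium`, `compare`, `demo`).

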