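---
title: "Reversal-related alpha desynchronization: models and methods"
author: "revalpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversal-related alpha desynchronization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revalpha)
```

## The scientific problem

During continuous observation of an ambiguous ("multistable") stimulus such
as stroboscopic alternative motion, perception alternates spontaneously
between two motion interpretations. Observers report each *endogenous*
reversal with a button press; a control condition applies *exogenous*
reversals by physically changing the stimulus. A robust electrophysiological
signature of the endogenous reversal is a gradual decrease of alpha-band
(8--14 Hz) power over posterior cortex beginning roughly one second before
the report — an event-related desynchronization (ERD). Aging studies ask
whether this topography shifts anteriorly in older adults, which would
indicate compensatory recruitment of additional alpha networks.

`revalpha` implements the full analysis chain for such experiments —
response-locked segmentation, Morlet-wavelet time-frequency decomposition,
decibel baseline normalization against perceptually stable periods, and the
group statistics — together with a synthetic continuous-EEG generator that
emulates the study design, so that every stage of the chain is testable
end-to-end without access to human recordings.

## The synthetic-data generator

`generate_session()` produces one 10-minute session at 500 Hz on eight
10--20 channels (F3/F4, C3/C4, P3/P4, O1/O2). Each channel is the sum of

* **1/f background noise** (4 µV RMS by default). Real resting EEG has an
  approximately power-law spectrum; the exact noise structure is not
  critical because all analyses are relative to a within-subject baseline.
* **a narrow-band alpha oscillation**: a cosine whose instantaneous
  frequency wanders around the 11 Hz center (SD 0.15 Hz, 0.5-s correlation
  time) and whose envelope waxes and wanes mildly (10% CV). The RMS
  amplitude has the posterior-dominant gradient of resting alpha
  (10 µV at P/O, 6--7 µV at F/C), matching the frontal < parietal baseline
  power ordering that the baseline-window analysis expects. The modulation
  depth was fixed so that a 300-ms window estimate at ~30 epochs resolves
  power changes to roughly ±0.15 dB; heavier waxing/waning is realistic for
  some participants but would make single-subject window estimates
  uninformative at the epoch counts this design yields.

**Events.** Endogenous dwell times (intervals between presses) are drawn
from a gamma distribution with shape 3 — dwell-time distributions in
bistable perception are positively skewed and gamma-like — with the scale
set so the mean reversal rate matches the group profile (7.18/min young,
4.83/min older; between-subject SDs 1.97 and 2.26). Only mean rates are
published for the emulated design, so the gamma family is a modeling
stand-in, not an inference about the data. Exogenous sessions contain
exactly 8 motion changes per minute; each change is placed at a uniformly
jittered position within its 7.5-s cycle rather than on a rigid grid. The
jitter matters twice: a fixed grid would be predictable for the observer,
and — more importantly for the analysis — it is geometrically required for
stable epochs to exist at all: with changes exactly 7.5 s apart the 5-s
reversal epochs tile the session leaving only 2.5-s gaps, and no 5-s
press-free epoch could ever be extracted. Presses follow each change at a
normally distributed latency (0.58 s young / 0.78 s older), and each change
is answered with the group's accuracy (98.55% / 93.46%); unanswered changes
are omissions. Stimulus-frame markers tick every 250 ms throughout,
mirroring the double-dot display cadence.

**ERD injection.** Around every button press the alpha envelope is
multiplied by a smooth gain window with floor `10^(depth/20)`, so a depth
of *d* dB produces exactly a *d* dB drop in alpha power at full
suppression. The endogenous profile ramps down (half-Gaussian) from 1 s
before the press, sits at full depth over [-0.6, +0.1] s, and recovers by
+0.5 s; the exogenous profile is steeper and shorter (ramp from -0.6 s,
plateau [-0.35, +0.1] s). The plateau was placed so that the *reversal*
analysis window (-350 to -50 ms) lies entirely at full depth — this makes
"recovered depth = injected depth" a well-defined calibration target —
while the *pre-reversal* window (-950 to -650 ms) catches the ramp,
reproducing the gradual build-up seen empirically. Overlapping windows
multiply. Default depths per group and condition encode the qualitative
topography under study: young adults posterior-dominant endogenous
suppression (O -2.0, P -1.2 dB), older adults anteriorized (F/C -1.5,
P -1.2, O -0.3 dB), and a *shared* posterior profile in the exogenous
condition (O -1.3, P -0.8 dB for both groups) — the stimulus-driven
response carries no group difference, which is exactly what makes the
endogenous-only three-way interaction a meaningful recovery target.
`run_study()` adds 0.3 dB between-subject SD to each ROI depth.

**Artifacts.** Blinks (frontal-weighted Gaussian bumps, ~150 µV), spikes
(120--200 µV, 1--3 samples) and slow drifts (110--160 µV over 2--5 s) occur
at Poisson times (defaults 2, 0.3, 0.2 per minute) and are returned in a
ground-truth log so rejection recall is measurable. What the generator does
*not* emulate: volume-conduction correlations between channels, true ocular
or muscle spectra, non-stationary alpha peak drift, or any coupling between
behavior and EEG beyond the injected ERD. Passing tests therefore certify
the *analysis chain*, not the realism of any particular human dataset.

## Segmentation

Reversal epochs span -3,000 to +2,000 ms around each press; epochs whose
window contains a second press are excluded (post-motor contamination).
Windows are half-open `[start, end)` in samples, with an event at time *t*
mapped to sample `round(t * fs)`; this makes boundary counting unambiguous
(note the rule is intentionally asymmetric: a press 2 s after another falls
outside the first press's window, while the first falls inside the
second's). Non-reversal ("stable") epochs reuse the same 5-s layout,
anchored on the 250-ms artificial markers, with the marker at 0 ms and the
baseline window at -500 to 0 ms before it; candidates are scanned greedily
earliest-first and kept if they contain no press and overlap neither a
reversal epoch nor a previously accepted stable epoch. The greedy scan is
deterministic and, for a fixed marker grid, maximal. The published
procedure does not state where the anchoring marker sits inside the 5-s
stable epoch; centering the layout identically to reversal epochs is our
interpretation and keeps one window bookkeeping for both epoch types.

Artifact rejection replaces manual visual inspection with its stated
operational core: any analyzed channel exceeding ±100 µV inside the
-1,500 to +200 ms inspection window flags the trial (spikes, drifts and
blink deflections all exceed this bound); an optional EOG blink-template
correlation provides a second route. This is a documented proxy — human
raters also catch subtler artifacts the amplitude rule misses.

Epoch-count equalization (`equalize_epoch_counts()`) randomly subsamples
every subject's surviving epochs to a common target (default: the minimum
surviving count in the condition), from a seeded stream, so group
comparisons cannot be confounded by trial counts. The published description
("random epoch exclusion" to a stated average) does not fix the target
policy; the minimum-count default is the simplest policy that guarantees
exact balance.

## Time-frequency decomposition

The complex Morlet kernel at center frequency *f* with *n* cycles is

$$\psi(t) = e^{2\pi i f t}\, e^{-t^2/2\sigma^2},\qquad \sigma = \frac{n}{2\pi f},$$

sampled on ±5σ and rescaled to unit energy ($\sum|\psi|^2 \Delta t = 1$).
With the analysis default *f* = 11 Hz, *n* = 7: σ ≈ 101 ms. Convolution is
performed in the frequency domain (FFT, pointwise product, inverse FFT) as
zero-padded *linear* convolution, center-aligned; trials are concatenated
per channel before the transform and re-cut afterwards. Concatenation makes
one long FFT per channel instead of one per trial; the price is edge
contamination within one kernel half-width (~150 ms) of each trial join,
which is irrelevant here because every analysis window lies ≥ 1 s from the
epoch edges (asserted by test). Power is averaged across trials,
$A(t) = \frac{1}{n}\sum_k |Z_k(t)|^2$; the *mean* (not the sum) keeps power
comparable across differing trial counts, which matters whenever
equalization targets differ between conditions. Powers are calibrated so a
sinusoid at the kernel's center frequency with RMS amplitude *r* µV reads
*r*² µV².

Baseline normalization is in decibels, `dB = 10 log10(power/baseline)`,
with the baseline the time-mean of stable-epoch power over -500 to 0 ms,
per subject, condition, channel and frequency. dB is computed per time
point after trial averaging, then averaged over the analysis windows;
baseline-window summaries stay in raw µV². Because the pipeline computes
dB after trial-averaging and selects trials before averaging, equalization
can equivalently be applied to stored single-trial window power — the
implementation exploits this to avoid holding all subjects' epoch arrays in
memory, and a test asserts exact agreement with the full transform chain.

Only the 11 Hz bin feeds the statistics: with 7 cycles the spectral SD is
*f*/*n* = 1.571 Hz, so 11 ± 2SD spans 7.86--14.14 Hz — 11 Hz is the only
center in the alpha range whose ±2SD band covers the whole traditional
8--14 Hz band. The full 8--14 Hz grid in 0.25 Hz steps is computed for
spectrogram export only. `wavelet_diagnostics()` measures both resolution
numbers from the sampled kernel itself: the spectral SD by a
weighted Gaussian fit to the magnitude spectrum's main lobe (robust to the
truncation tails that bias moment estimators), and the temporal width as
twice the time at which the squared (power) envelope falls to $e^{-2}$,
giving $2\sqrt{2}\sigma \approx 286$ ms. An amplitude-envelope reading of
the same folding criterion would give ≈ 405 ms; the power-envelope reading
is implemented because it matches the ≈ 300 ms value this wavelet is
conventionally quoted at.

## Statistics

`mixed_anova()` implements the balanced split-plot decomposition (one
between-subjects factor, one or two within-subjects factors) from the
multivariate linear model with sum-to-zero coding and Type III hypotheses,
projecting hypothesis and error cross-products onto orthonormal within
contrasts. It reports, per effect: F, p, partial η², the Greenhouse-Geisser
ε (from the eigenvalues of the projected error covariance; exactly 1 for
1-df effects), GG-corrected df and p, and Mauchly's sphericity p. The
`p_inference` column applies the GG correction *only when Mauchly indicates
a sphericity violation* (p < .05): applying GG unconditionally under a
spherical null is measurably conservative (empirical α ≈ 0.02 at nominal
.05 in our calibration), while the conditional rule holds ≈ 0.045 over
2,000 null simulations. The engine agrees with `car::Anova` (the reference
implementation used in the test suite) to ~1e-6 on random designs,
balanced or not.

The linear-trend group contrast scores each subject on the linear
anterior-to-posterior gradient of the reversal-minus-pre-reversal change
and tests the group difference of that score (1-df F), the statistic that
captures "suppression increases towards occipital in young adults but
towards frontal in older adults". Planned pre-to-reversal comparisons use
paired t with Hedges $g_{av}$ — mean difference over the average of the two
condition SDs, times the small-sample correction $1 - 3/(4(n-1)-1)$.
Post-hoc pairwise ROI comparisons are Bonferroni-corrected with a
configurable family size; the default family is all pairwise ROI tests per
condition (12 with two groups), consistent with a corrected threshold of
p < .004 at α = .05. Group behavioral comparisons use an independent t with
pooled-SD Cohen's d for reversal rates, and Mann-Whitney U for RT and
accuracy (whose variances differ between age groups; a Levene check
centered on means is reported alongside either method). Dwell-time
regressions fit each group × ROI ordinary least squares of mean dwell time
on reversal-window dB.

## The simulated study and its calibration

`run_study()` simulates every subject's two sessions, segments, rejects,
equalizes (separately for reversal and stable sets within each condition),
summarizes, and runs the full battery; a master seed spawns per-subject and
per-stage sub-streams, so adding subjects never perturbs existing ones and
re-running a config reproduces every table exactly. Degenerate designs
(an empty group, subjects without usable epochs) skip the affected
statistics with explicit notices rather than failing.

Simulation sizes used by the test suite were chosen as the package's own
trade-off between statistical resolution and runtime on a single CPU:
200 event-stream replicates for the reversal-rate check (SE ≈ 0.06/min),
10 full 12+12-subject studies for the topography-interaction power check
(≥ 80% maps to ≥ 8/10; the injected pattern yields an interaction far from
the decision boundary), and 2,000 summary-level null experiments for the
type-I calibration (SE ≈ 0.5 percentage points). The null calibration
generates subject × cell summaries directly (subject intercept plus the
mean of 10 epoch-level draws) rather than full EEG, which is what makes
2,000 replicates feasible; it tests the inference rule, while the full-EEG
simulations test the chain that produces its inputs.

## Numerical choices and limitations

* FFT sizes are padded to 5-smooth lengths; convolution is exact linear
  convolution regardless of padding (asserted against a direct time-domain
  oracle to 1e-8).
* Events map to samples by rounding; all windows are half-open in samples.
  Ties at window boundaries therefore never double-count.
* dB requires strictly positive baselines; a zero/negative baseline names
  the offending channel and frequency instead of propagating NaN.
* EDF export quantizes to 16 bits over a per-channel symmetric range
  (round-trip error below `range/32767` µV); header date fields are fixed
  so regeneration is byte-identical. Only whole-second recordings are
  written (one-second data records).
* The generator's channels are independent conditional on their profiles;
  scalp covariance, reference choice and ocular propagation are out of
  scope, as are individual alpha-frequency estimation and sub-band
  analyses.
* Recovered ERD depth is slightly attenuated (≈ 0.1--0.2 dB at -6 dB) by
  the in-band 1/f noise floor; this is inherent to any power-ratio measure
  and stays well inside the ±0.5 dB recovery tolerance at the default
  signal-to-noise ratio.

## A worked example

```{r example, eval = FALSE}
library(revalpha)

cfg <- simulation_config("endogenous", "young",
                         erd_depth = c(F = 0, C = 0, P = 0, O = -3),
                         seed = 42)
ses <- generate_session(cfg)

rev <- reject_artifacts(extract_reversal_epochs(ses$recording, ses$events))
non <- reject_artifacts(extract_nonreversal_epochs(ses$recording,
                                                   ses$events, rev))
tfr <- tfr_epochs(rev, freqs = 11)
bl <- baseline_power(tfr_epochs(non, freqs = 11))
average_windows(baseline_normalize(tfr, bl), "endogenous")
```

The occipital reversal-window value lands within ±0.5 dB of the injected
-3 dB; frontal channels (no injection) stay near 0 dB. A full simulated
group study is one call: `run_study(study_config(seed = 1), out_dir)`.
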