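---
title: "Assessing chair-based exercise quality from joint angles and sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing chair-based exercise quality from joint angles and sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbeqc)
```

## The problem

Chair-based exercises (CBE) are a mainstay of strength and mobility training
for frail older adults, but their benefit depends on being executed with the
right form. A practical monitoring system uses a single consumer camera: a
pose-estimation model (MediaPipe layout) provides eight 2D lower-body
keypoints per frame — shoulders (landmark IDs 11/12), hips (23/24), knees
(25/26) and ankles (27/28) — from which joint angles are computed by vector
geometry. Surface EMG (sEMG), recorded at 1000 Hz in mV, serves as the
physiological reference: correctly executed movements recruit the target
muscles more strongly than typical incorrect forms.

`cbeqc` implements this analysis end to end: joint-angle kinematics, the
sEMG conditioning chain, windowed time/frequency features, an SVM
correctness classifier evaluated by leave-one-out cross-validation (LOOCV),
and cohort-level paired statistics. Because recordings of this kind are not
publicly distributable, the package ships a synthetic-cohort generator
calibrated from the published per-movement summary table (nine movement
conditions, M1-A through M8), so every stage is testable and the published
benchmark quantities can be recomputed from scratch.

## Joint-angle kinematics

Two angle kinds are supported:

* **Vertex angle** at the middle point `b` of a chain `a–b–c` (e.g.
  hip–knee–ankle = knee angle):
  $\theta = \arccos\left(\frac{(a-b)\cdot(c-b)}{\lVert a-b\rVert\,\lVert c-b\rVert}\right)$,
  in $[0^\circ, 180^\circ]$. The cosine is clamped to $[-1, 1]$ before the
  arccosine so collinear configurations are safe under floating point.
* **Segment inclination** of `p→q` against the image vertical (y grows
  downward in normalised image coordinates), also in $[0^\circ, 180^\circ]$.
  Swapping the endpoints maps $\theta \mapsto 180^\circ - \theta$.

The default registry holds six angles — left/right shoulder–hip–knee,
left/right hip–knee–ankle, left/right knee–ankle inclination — and is fully
configurable, because the exact angle definitions behind a given deployment
vary. The "knee–ankle angle" used for movement M5 is genuinely ambiguous
(vertex at the knee, or inclination of the shank segment); both are
implemented and the package defaults to the inclination reading, selectable
per analysis. Per-repetition summaries are plain frame means.

## sEMG conditioning chain

The chain is fixed: 50 Hz notch → 20–450 Hz Butterworth bandpass → windowed
RMS (100 ms windows, 50% overlap). Scalar summaries (overall mean RMS,
per-repetition peak RMS) are computed on this un-normalised envelope; a
duration-normalised variant (affine index mapping to $[0,1]$, linear
resampling to 500 points, Gaussian smoothing with $\sigma = 10$ samples) is
produced for visual cross-trial comparison only.

Published descriptions of such chains typically omit filter details, so the
package fixes defensible ones and exposes them as arguments:

* Notch: second-order IIR (RBJ biquad) with quality factor $Q = 30$
  (≈1.7 Hz bandwidth at 50 Hz), applied zero-phase. Measured response:
  ≥ 20 dB rejection at 50 Hz, < 1 dB loss 20 Hz away.
* Bandpass: Butterworth order 4 per pass, applied forward–backward
  (zero-phase, effective order 8). Measured response: ≥ 20 dB attenuation at
  5 Hz and 490 Hz, ≤ 1 dB ripple at 100 Hz.
* Zero-phase filtering uses odd-extension edge padding (the plain
  reverse–filter–reverse scheme leaves edge transients large enough to break
  the stopband figures on 2 s records).
* RMS windowing: window count is $\lfloor (N - W)/H \rfloor + 1$ with
  $W$ = window samples and $H$ = hop samples; trailing samples that do not
  fill a window are dropped — the simplest deterministic rule.

Repetition segmentation (the protocol has 10 repetitions per ~20 s trial)
is not part of the published chain, so the package's own detector is used
when explicit repetition markers are absent: Gaussian-smooth the envelope
($\sigma = 5$ windows), threshold at the midpoint of the 10th and 90th
percentiles, merge gaps shorter than 0.25 s, drop segments shorter than
0.25 s. Markers, when present, always take precedence. Peak extraction uses
the raw (unsmoothed) envelope.

## Windowed features and classification

Angle series are cut into 30-frame (1 s at 30 fps) windows with 15-frame
hop. Each window yields ten features: mean, minimum, maximum, median and SD
(population convention, denominator $n$, used consistently for the spectral
SD too), plus five Welch-PSD features — mean, peak and minimum in-band
power, SD of power, and median frequency (the smallest in-band frequency at
which cumulative in-band power reaches half the total).

Two numerical choices deserve note. First, the nominal 1–20 Hz analysis
band exceeds the 15 Hz Nyquist frequency of 30 fps video; the band is
clipped to $[1, \mathrm{fps}/2)$ with a warning, because only realisable
bins exist. Second, Welch's method on a 30-sample window degenerates to a
single Hann-tapered, mean-detrended segment; sub-segmenting would leave a
frequency resolution too coarse to be useful, so the single-segment form is
used deliberately.

The classifier is a C-SVM with RBF kernel ($C = 1$,
$\gamma = 1/(p \cdot \mathrm{Var}(X))$ on standardised features, i.e.
$\approx 1/p$), with class weights inversely proportional to class
frequencies. Features are standardised with training-set mean/SD *inside
each cross-validation fold*, so no information leaks from the held-out
unit. LOOCV is available at two granularities: `"sample"` holds out one
feature window at a time (the protocol behind the published accuracy
figures — note windows from one participant then appear on both sides of
every split), while `"participant"` holds out whole participants and
quantifies how much that leakage flatters the sample-level number. Both are
first-class and can be reported side by side.

## The synthetic cohort generator

The generator's defaults are the study conditions: 20 participants, 10
repetitions per condition, ~20 s trials, 30 fps video, 1000 Hz sEMG, 50 Hz
powerline contamination. Per (movement, condition) cell it reproduces the
published summary-table statistics:

* **Angles.** The scored angle follows $\theta_t = \mu_p + \varepsilon_t$
  with $\mu_p \sim N(\mu, \sigma_b^2)$ drawn once per participant and
  $\varepsilon_t \sim N(0, \sigma_w^2)$ per frame. Landmarks are placed so
  the registry angle computed from them equals $\theta_t$ exactly (the
  moving endpoint of the scored angle rotates on a fixed-length limb; the
  other landmarks hold a plausible static seated pose). The printed table
  SDs are across-participant spreads, so the default maps them to
  $\sigma_b$ with $\sigma_w = 0.5^\circ$ — a landmark-jitter scale typical
  of pose estimation on static postures; the published source does not
  report within-trial variance, so this surrogate is exposed as
  configuration (`variance_mode`, `jitter_sd`). Realisations outside
  $(0^\circ, 180^\circ)$ are clipped with a warning.
* **sEMG.** Each trial is an amplitude-modulated burst train: Hann
  envelopes at 60% duty cycle (matching slow, repetitive seated exercise)
  over a 20–450 Hz band-limited Gaussian carrier, plus a powerline sinusoid
  (0.05 mV default) and baseline noise (0.005 mV). The burst amplitude is
  self-calibrated: the unit-amplitude clean burst train is passed once
  through the conditioning chain and scaled so the post-chain overall mean
  RMS equals the participant's target strength — exact for zero
  noise/powerline, and within the 5% contract otherwise. Participant
  strengths for the two conditions are drawn from a bivariate normal with
  the published condition means/SDs and correlation 0.8 (stronger
  participants are stronger in both forms), truncated at 0.005 mV to keep
  amplitudes positive.
* **Reproducibility.** One master seed; each (participant, movement,
  condition, repetition) draw uses a counter-derived sub-seed, so identical
  specifications give byte-identical cohorts and partial regeneration
  reproduces the same draws.

What the generator does **not** emulate: occlusion and visibility dropouts,
lighting-dependent landmark bias, movement-phase structure within a
repetition (the angle process is stationary around $\mu_p$), inter-muscle
crosstalk, electrode-impedance drift, and any systematic difference in
waveform *shape* between conditions. Passing tests therefore demonstrate
that the pipeline recovers the statistical structure it assumes — condition
separations of the published size at the published noise scales — not that
it would classify real recordings at the same accuracy.

## Benchmark recomputation

`scripts/acceptance.R` regenerates calibrated cohorts and recomputes the
headline quantities: the M5 LOOCV accuracy and the nine-movement average
accuracy (surrogate design: between-participant SD 0, frame jitter equal to
the printed per-condition SDs, so windows carry exactly the
printed-magnitude class separation), the paired t-test on M3 per-participant
mean RMS, angle-mean recovery for M1-A and M8, and sEMG-mean recovery for
M2. Problem sizes are scaled to desk scale — 20 participants throughout,
1–5 repetitions per condition and 10 s trials rather than 10 × 20 s — which
leaves every separation and standard-error argument intact while keeping a
full run under two minutes; the same holds for the test suite's smaller
cohorts. The package reports these quantities only as computed at run time;
nothing is hard-coded.

```r
profs <- reference_profiles("M5", variance_mode = "within")
spec  <- cohort_spec(n_participants = 20, reps_per_condition = 2,
                     trial_duration = 10, seed = 2)
coh   <- generate_cohort(profs, spec, components = "landmarks")
ft    <- build_feature_table(coh)
loocv(ft, granularity = "sample")
```

## Known limitations

* The six-angle registry is a surrogate for deployment-specific angle
  definitions and must be adapted to any real landmark stream.
* Sample-level LOOCV inherits participant leakage by construction; use
  `granularity = "participant"` for a generalisation estimate.
* The sEMG model is amplitude-only; spectral EMG features (e.g. fatigue
  shifts of the median frequency) are outside its scope.
* No MVC normalisation: absolute mV comparisons across participants carry
  the full inter-individual variability, which is precisely why the paired,
  within-participant design is used for condition comparisons.
* Stage outputs of `run_pipeline()` are recomputed on every call; runs are
  deterministic under a fixed seed but no cross-run caching is attempted.
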