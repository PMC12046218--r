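---
title: "Methods: photometry correction, escape segmentation, and the synthetic looming assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry correction, escape segmentation, and the synthetic looming assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoloom)
```

## The assay and the analysis problem

In the looming-stimulus assay a mouse explores a rectangular arena
(61 cm x 20.3 cm by default) with a shelter at one end and a "threat
zone" at the other, beneath a display. After a 5-minute free-exploration
period, the first tracked position inside the threat zone triggers a
train of five dark expanding ("looming") disks — each growing linearly
from 0 to 19.5 cm over 0.25 s, holding for 0.25 s, with a 0.5-s
offset-to-onset inter-stimulus interval — which reliably drives flight to
the shelter. Fluorescence from a dopamine sensor is recorded throughout
by two-channel fiber photometry: a 465-nm excitation channel carries the
sensor signal, and a 405-nm isosbestic excitation channel carries the
same motion and bleaching artifacts but no dopamine-dependent signal.

The analysis has to answer, per animal: how large was the
stimulus-evoked dopamine transient, when did the escape start, how
vigorous was it — and, across animals, whether transient amplitude
predicts escape latency and vigor, whether responses habituate across
the disk train, and whether escape probabilities differ between
treatment arms. `photoloom` implements that chain end to end, plus a
synthetic-session generator with full ground truth so every stage can be
validated without recorded data.

## Photometry correction and normalization

The reference model is a first-order (linear) alignment of the 405-nm
channel to the 465-nm channel, fitted by ordinary least squares over the
whole recording and subtracted:

$$\Delta F_t = F^{465}_t - (\hat\beta_1 F^{405}_t + \hat\beta_0).$$

We fit the reference *to* the signal (rather than rescaling the signal)
so that sensor transients, which exist only in the 465-nm channel, are
not distorted by the fit; they leak into the coefficients only through
their small covariance with the reference. ΔF is used unnormalized — no
division by a baseline fluorescence — because the subsequent z-scoring
removes scale anyway. Whole-recording fitting (rather than per-epoch)
uses the longest possible artifact sample; its cost is a slight,
transient-proportional leakage into the fitted slope, which is
negligible at realistic noise levels (the noiseless limit is discussed
under *Numerical behavior* below).

The ΔF trace is then z-scored against an epoch: `z = (ΔF - m) / s` with
`m`, `s` the mean and sample standard deviation (n−1) of the ΔF samples
inside the epoch window, applied to the whole trace. **The default epoch
is the 10 s immediately before the trigger** (`epoch_pre = 10`,
`epoch_post = 0` in `loom_config()`). An earlier design normalized over
the full peri-trigger analysis window, but including the evoked response
in the epoch makes the normalizing `s` transient-dominated, so the
reported z amplitude saturates with the true response size; in the
noise-free limit the recovered amplitude becomes a constant independent
of the injected one. Normalizing to the pre-stimulus baseline keeps the
z scale response-independent and is the convention used for event-locked
z-scores generally. A corollary worth keeping in mind for real data:
the per-session z scale is set by each session's baseline noise, so
cross-animal amplitude comparisons implicitly assume comparable baseline
variability.

## Transients, baselines, and event alignment

Peaks are local maxima that clear a topographic-prominence floor
(default 0.5 z) and a minimum separation (0.25 s; when two candidates
are closer, the larger wins). Prominence is computed on the full trace
and the search window only selects peaks — computing prominence inside a
short window would penalize a transient whose flanks extend past the
window edge. Plateau ties resolve to the earliest sample.

The pre-stimulus baseline statistic is the amplitude of the largest
detected peak in the 1-s epoch immediately before disk-1 onset,
approximating the size of spontaneous events and noise; if no local
maximum qualifies (e.g. a monotone ramp), the window maximum sample is
used and flagged. Per-disk response amplitudes use the same statistic on
the 1-s half-open window after each disk onset — the same window length
and the same extraction rule as the baseline, so that under the null
(no evoked transient) the disk and baseline statistics are exchangeable
and the paired disk-versus-baseline test is calibrated. The 1-s response
window brackets the sub-second stimulus-to-peak latencies typical of
dopamine-sensor responses to looming disks.

Event-aligned matrices use nearest-sample indexing (no interpolation:
amplitudes are preserved and the grid error is at most half a sample).
Events without full pre/post coverage are dropped rather than padded,
because padding would bias the SEM row.

## Behavior: kinematics and segmentation

Positions are smoothed with a centered 0.2-s moving average before
differentiation (suppresses tracking jitter at 30 Hz without blunting
sub-second escape ramps); speed is the magnitude of the centered finite
difference, acceleration the centered difference of speed, one-sided at
the endpoints.

An escape requires shelter entry within 10 s of disk-1 onset. Detection
is anchored by the first sustained (≥ 0.2 s) crossing of 10 cm/s after
disk-1 onset; the reported onset is then backtracked to where speed last
left a 2 cm/s resting floor. The anchor alone would inherit the ramp's
time-to-threshold — up to ~0.3 s for low-acceleration escapes — whereas
the backtracked onset marks movement initiation and recovers programmed
latencies to within a tracking sample or two. Escape latency is
onset − disk-1 onset (the movement-onset definition; shelter entry is
reported separately, with entry defined as the centroid crossing the
shelter boundary, no dwell requirement). Movement bouts are maximal
intervals with speed ≥ 2 cm/s, merged across gaps < 0.5 s, kept when
their peak reaches 20 cm/s; freezing is speed < 1 cm/s sustained ≥ 1 s
outside the shelter (immobility inside the shelter is sheltering, not
freezing). None of these thresholds are dictated by the assay hardware;
all live in `loom_config()`.

A mouse is an *escaper* when its threat trial yields an escape bout;
cohort correlations between disk-1 amplitude and escape latency, peak
velocity and peak acceleration are computed over escapers only, the
repeated-measures ANOVA on baseline + five disk amplitudes over all
animals, and two-arm escape counts go through the 2x2 Pearson
chi-squared test.

## The statistical layer

Pearson correlation (two-sided p from the t transform, n−2 df),
pooled-variance unpaired t (df = n1+n2−2; pooled, not Welch, matching
the df conventions of this literature), paired t, and the 2x2 Pearson
chi-squared *without* continuity correction — the uncorrected statistic
on the escape counts 8-of-10 vs 1-of-8 equals 8.10, which is the
convention the printed values follow. Repeated-measures ANOVA is
computed by direct within-subject sums-of-squares decomposition; each
effect is tested against its own subject-by-effect interaction stratum
with sphericity-assumed degrees of freedom (one-way: `k-1`,
`(k-1)(n-1)`). Bonferroni pairwise comparisons multiply each raw paired-t
p by the number of comparisons actually performed (five disk-vs-baseline
comparisons in the one-way design), capped at 1. Scalar tests delegate
to the standard R implementations; the ANOVA decomposition is
cross-checked against `aov()` error strata in the test suite.

## The synthetic session generator

The generator emulates the statistical structure the analysis assumes,
not the physics of the instruments:

* **Photometry** (100 Hz default): each channel is baseline +
  exponential photobleaching + a shared Ornstein–Uhlenbeck (OU) motion
  artifact (sd 1.0 a.u., correlation time 0.5 s) + white noise (sd
  0.2 a.u.); sensor transients — unit-peak difference-of-exponentials
  kernels, rise 0.1 s / decay 0.8 s — are added to the 465-nm channel
  only. Both channels carry the *identical* artifact realization, which
  is what makes reference-channel regression effective; with the default
  noise mix the correction removes over 90% of the shared-artifact
  variance. Motion artifacts several-fold larger than the white
  measurement noise are typical of freely moving recordings.
* **Trajectory** (30 Hz default): reflected-OU velocity exploration
  (typical speed 6 cm/s, stationary and with tunable bout statistics),
  one scripted vigorous movement bout (peak 30 cm/s) during the 5-min
  exploration period, and a scripted smooth approach that delivers the
  mouse to the threat zone 5–20 s after the exploration period ends; the
  ground-truth trigger is the first in-zone tracking sample, wherever it
  occurs.
* **Stimulus coupling**: the disk-1 transient is injected 0.3–0.6 s
  (uniform) after disk-1 onset; with the kernel's 0.24-s onset-to-peak
  delay the simulated stimulus-to-peak latencies bracket the 0.6–0.7 s
  values typical of this assay. The transient amplitude (z units) is
  drawn from N(3, 1.5²) — the between-animal spread implied by this
  assay's printed cohort statistics (mean ± SEM of ~2.95 ± 0.45 over 11
  animals) — and linearly programs the escape kinematics: latency slope
  −0.8 s/z with residual sd 0.6 s (population R² = 0.8 around a ~3.8-s
  mean), peak velocity slope +8 (cm/s)/z, residual 7.5 (R² ≈ 0.72 around
  ~56 cm/s), peak acceleration slope +80 (cm/s²)/z, residual 75
  (R² ≈ 0.72 around ~364 cm/s²). Programmed latencies below 0.5 s are
  clipped and flagged.
* **Escape script**: stimulus-locked arrest from trigger to the
  programmed onset, then a straight run to the shelter with a
  raised-cosine speed profile: ramp-up whose duration is set by the
  programmed peak acceleration, a cruise at the programmed peak velocity
  of at least 0.25 s (longer than the position-smoothing window, so the
  recovered peak is not attenuated), and a raised-cosine ramp-down
  absorbing the remaining distance. When the requested ramp does not fit
  the available distance it is capped and the realized peak acceleration
  recomputed analytically and flagged. Non-escapers arrest briefly and
  resume exploration that never enters the shelter.

The generator reproduces what the analysis needs — shared artifacts,
bleaching, transient kinetics, arrest-then-flight escapes, programmed
couplings — and deliberately omits photon-shot-noise statistics,
hemodynamic contamination, tracking dropouts and pose/orientation
structure. Passing tests therefore validate the *pipeline's logic and
calibration*, not its robustness to every pathology of real recordings.

## Numerical behavior and degenerate inputs

* A constant (or near-constant) reference channel makes the fit
  underdetermined and raises a degenerate-fit error; NaNs are reported
  with the first offending index.
* A constant ΔF within the z-scoring epoch raises an error rather than
  dividing by zero.
* In an exactly noise-free recording the whole-recording fit's
  transient leakage becomes the dominant "noise" and the per-session z
  scale becomes amplitude-dependent; tests of the noiseless-line
  property therefore keep a small white-noise floor, which is also the
  physically sensible limit.
* A repeated-measures matrix whose conditions are identical per subject
  yields F = 0, p = 1 (rather than 0/0); a zero residual stratum with a
  nonzero effect raises a singular-error-term error.
* All statistic-bearing windows are half-open on the right so adjacent
  windows never share samples.

## Problem sizes used by the tests and acceptance script

Unit tests run on scaled-down sessions (20-s exploration, 25-s
post-trigger recording) chosen so that every analysis window is still
fully covered. The acceptance computations use the full study
conditions: 250 default-noise sessions for parameter recovery in the
test suite (the 50-session block correlation has a sampling sd of
~0.025, so the larger block pins the population value down; the
acceptance script reports the 50-session figure), 100
cohorts of 11 escapers for coupling recovery, 2,000 replicates for null
calibration (each simulating 16 photometry epochs of 17.5 s — the
trajectory does not enter either null statistic, since with zero
coupling the programmed kinematics are independent of the photometry by
construction, so simulating it would only add cost), and 100-seed
property sweeps for the statistical oracles.

## Known limitations

* The escaper criterion (shelter entry within 10 s) and every
  behavioral threshold are configurable conventions, not measured
  constants.
* The simulator's inter-animal variability enters only through the
  amplitude draw and kinematic residuals; real cohorts have additional
  variance components (sensor expression, fiber placement) that are not
  modeled.
* With the default 0.8-s transient decay, the tail of a disk-1 response
  extends into the disk-2 analysis window; the per-disk statistic
  faithfully reports that elevated signal. Distinguishing tail from
  genuine disk-2 response would require deconvolution, which is out of
  scope.
* Sample R² over cohorts of 11 animals is intrinsically variable (its
  sampling sd around a true value of 0.8 is roughly 0.12), so
  cohort-level coupling estimates should be read with that spread in
  mind.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
s <- simulate_session(seed = 42)          # full synthetic session
res <- run_simulated_session(s)           # correct, z-score, segment, measure
print(res)

co <- simulate_cohort(11, seed = 7)       # 11-mouse cohort
print(run_cohort(co))                     # correlations, RM ANOVA, comparisons

escape_contingency(8, 10, 1, 8)           # two-arm escape counts
```
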