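# photoloom

Analysis of two-channel fiber photometry recorded during looming-visual-threat
assays in mice — for researchers who record dopamine-sensor (or similar)
fluorescence while a mouse, exploring a shelter/threat-zone arena, is
challenged with a train of overhead expanding dark disks and flees to shelter.

The package covers the full chain:

* **Isosbestic correction.** The 405-nm reference channel is aligned to the
  465-nm signal channel by a first-order least-squares fit and subtracted,

  ΔF<sub>t</sub> = F<sup>465</sup><sub>t</sub> − (β̂₁ F<sup>405</sup><sub>t</sub> + β̂₀),

  removing the motion artifact and photobleaching shared by the two
  excitation wavelengths while leaving sensor transients intact. The ΔF trace
  is z-scored against the 10-s pre-trigger baseline epoch:
  z = (ΔF − m) / s with m, s from the epoch only.
* **Transient analysis.** Prominence-based peak detection; the pre-stimulus
  baseline statistic (largest peak in the 1 s before disk-1 onset); per-disk
  response amplitudes over the same 1-s window convention; event-aligned
  mean ± SEM matrices.
* **Stimulus model.** The five-disk looming train (0.25 s expansion to
  19.5 cm, 0.25 s hold, 0.5 s ISI) scheduled from the threat-zone trigger,
  and the viewing geometry: a 19.5-cm disk at the 40.5-cm display height
  subtends 2·atan(19.5/81) ≈ 27° of visual angle.
* **Behavior.** Smoothed finite-difference kinematics; threat-zone trigger
  detection after the 5-min exploration period; escape bouts (sustained
  10 cm/s anchor, onset backtracked to movement initiation, shelter entry
  within 10 s) with latency, peak velocity and peak acceleration; spontaneous
  movement bouts; freezing; escaper classification.
* **Statistics.** Pearson correlation, paired / pooled-variance t tests,
  one- and two-way repeated-measures ANOVA with Bonferroni pairwise
  comparisons against baseline, and the uncorrected 2×2 Pearson χ² on escape
  counts (8-of-10 vs 1-of-8 gives χ²(1) = 8.10 exactly).
* **Synthetic sessions.** A generator with complete ground truth — shared
  OU motion artifact, exponential bleaching, difference-of-exponentials
  transients, reflected-OU exploration, scripted threat-zone approach,
  arrest-then-flight escapes, and a programmable linear coupling between
  transient amplitude and escape kinematics — so every stage is testable
  without recorded data.

## Worked example

```r
library(photoloom)

s   <- simulate_session(seed = 42)   # full synthetic session + ground truth
res <- run_simulated_session(s)      # correct -> z-score -> segment -> measure
print(res)
#> Session m1: trigger 300.00 s, baseline 3.05 z, disk-1 amplitude 7.06 z,
#>   escape latency 1.77 s (peak 75.5 cm/s)
```

The ground truth behind this session programmed a stimulus transient of
5.06 z, an escape latency of 1.80 s and a peak velocity of 75.5 cm/s: the
pipeline recovers the latency within one tracking sample and the peak
velocity exactly; the z amplitude is the peak of the baseline-normalized
trace (transient plus baseline noise), which tracks the injected amplitude
linearly across sessions.

```r
co <- simulate_cohort(11, seed = 7)  # 11 escapers with coupled kinematics
print(run_cohort(co))
#> Cohort: 11 mice, 11 escapers
#>   disk-1 amplitude vs escape metrics (escapers only):
#>     latency            R^2 = 0.682, p = 0.001743 (n = 11)
#>     peak_velocity      R^2 = 0.418, p = 0.0316 (n = 11)
#>     peak_acceleration  R^2 = 0.810, p = 0.0001604 (n = 11)
#>   amplitude ~ condition RM ANOVA: F(5,50) = 16.517, p = 1.329e-09
```

The generator programmed a population amplitude–latency R² of 0.8; the
cohort estimate (0.682 here) scatters around it with the sampling spread
expected at n = 11. The ANOVA separates the disk-1 response from baseline
and later disks.

```r
escape_contingency(8, 10, 1, 8)      # two-arm escape counts
#> Pearson chi-squared (no continuity correction): chi2(1) = 8.100, p = 0.004427
```

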