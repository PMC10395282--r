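---
title: "Continuous driver task load and eye-event-locked EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous driver task load and eye-event-locked EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driveload)
```

# The problem

During natural driving there are no experimenter-controlled stimuli to
time-lock the EEG to. Two ideas make continuous analysis possible anyway:

1. **Spatial task-load mapping.** The drive is cut into 10-m track
   segments. For each segment, frontal theta power (4–7 Hz; F3, Fz, F4,
   FC1, FC2) and posterior alpha power (8–12 Hz; P3, Pz, P4, PO9, PO10,
   O1, Oz, O2) are extracted from a continuous Morlet wavelet transform
   (2–30 Hz in 29 linear steps), z-scored over the whole recording,
   segment-averaged and smoothed over ±50 m. The per-segment score
   `alpha_z − theta_z` (median across subjects) is split into rank
   terciles: alpha-dominant segments are *low* load, theta-dominant
   segments *high* load.
2. **Eye events as self-generated markers.** Blinks (re-opening of the
   eye) and fixation onsets (saccade offsets) mark moments of renewed
   visual intake. ERPs locked to them (bERPs/fERPs: lambda/P1, N1,
   parietal and occipital P2, fronto-central N2), lateralized components
   relative to saccade direction (phasic ERL ≈ N1pc; tonic pre-saccadic
   ERL; CNV), and saccade-locked spectral perturbations (ERSP, contra-
   minus ipsilateral) quantify processing and spatial attention per load
   level and per saccade type (outward = away from the road center,
   inward = back to it).

The package implements both layers plus the statistical machinery
(repeated-measures ANOVA with Greenhouse–Geisser correction, adjusted
partial eta squared, jackknife peak scoring, cluster-based permutation
tests), and a synthetic driving-EEG generator with complete ground truth
so that every stage is testable without any recorded data.

# The synthetic generator

`simulate_route()` builds a freeway/rural/city/fog/construction profile
with a continuous demand function `u(d) ∈ [0, 1]`;
`simulate_telemetry()` drives it (velocity follows a demand-dependent
target through a 3-s lag; steering is low-pass noise whose amplitude
grows with demand; 100-Hz transcription; trigger points at known track
positions). `simulate_recording()` renders 32-channel, 500-Hz EEG:

* **1/f background**, per channel, RMS = 7 µV / SNR. The SNR dial is
  defined as the largest injected component (the 7-µV lambda response)
  over the background RMS.
* **Posterior alpha**, one narrowband (8.5–11.5 Hz) carrier per
  hemisphere sharing 70% of their variance (`alpha_coherence = 0.7`).
  Posterior alpha is strongly bilaterally coherent in real EEG;
  independent hemispheres would also make every contra−ipsi derivation
  far noisier than real data. The envelope falls with demand
  (`alpha_amp = 2 µV` at demand 0, −50% across the range — alpha is
  strongly desynchronized during active driving, hence the low resting
  amplitude). **Frontal theta** (4.5–7 Hz) rises with demand.
* **Blinks**: Gaussian EOG deflections (100 µV at Fp1/Fp2, σ = 50 ms),
  renewal process with dead time whose rate falls with demand
  (12.2 − 4.5·u per minute — matching the observed ≈11 → 8.6/min span
  across load terciles).
* **Gaze excursions**: an outward saccade (erf-shaped horizontal-EOG
  step, F7/F8 dipolar, three amplitude classes 40/80/120 µV, 40-ms
  duration), a uniform 0.4–1.2-s fixation dwell, then the inward return.
  Excursion rate rises with demand (13.5 + 5·u per minute). Saccade
  direction is random; the inward saccade reverses it.
* **Event-locked components** at amplitudes that follow the canonical
  load/type pattern (blink and fixation N1/P2/N2 and lambda; CNV and a
  two-window tonic ERL before saccades — much larger before inward
  ones; a phasic ERL after fixations — larger after outward ones; and a
  35% contralateral alpha suppression during the 800 ms before inward
  saccades). All scalp patterns are zero-mean (average-reference
  invariant); every amplitude receives one additive N(0, 0.2 µV) draw
  per subject and component.

`GroundTruth` carries the true event table with load labels, per-segment
demand terciles, the source traces, topographies, and the per-component
jitter draws. Event schedules and noise are drawn from separate RNG
streams, so `render = "events_only"` produces a noiseless *twin* of any
recording — identical events and injected components, no background and
no oscillations. The twin is the natural recovery reference: its
measured values are the injected amplitudes of that exact dataset.

## What the generator does *not* emulate

No volume-conducted spatially-correlated background (channels carry
independent 1/f noise plus the structured sources), no non-stationary
artifacts other than ocular ones, no microsaccades or vertical saccades,
no eye-tracker-grade kinematics, no pupil dynamics, and no real
between-subject topography variability. Passing tests therefore show
that the algorithms recover the structure they assume; they do not show
robustness to every failure mode of real recordings.

# The analytic forward model

With overlapping components, the *nominal* amplitude of a component is
not what any measurement convention can read off the recording: the
pre-saccadic CNV sits under the fixation baseline window (−200..0 ms is
saccade occlusion, i.e. 40 ms after the CNV's own support), and within a
gaze excursion the outward fixation's epoch contains the inward
saccade's components at a dwell-distributed lag.
`expected_component_measures()` therefore predicts, per measure and
condition, the value the measurement conventions see: deterministic
within-excursion lags are applied exactly, dwell-distributed lags are
box-convolved over the uniform dwell, lateralized components leak into
the occipital cluster with their known 1/3 topography weight, and the
±12-ms peak-scoring smoother is applied on the same 2-ms grid as the
measurements. For a finite cohort the injected amplitude additionally
includes the cohort's realized mean jitter draw (`jitter =` argument).

The analytic model marginalizes over the dwell distribution, which a
finite condition cell does not: with tens of events per cell the
realized lag structure departs from the marginal by up to a few tenths
of a microvolt. Parameter-recovery tests therefore compare the noisy
pipeline against the noiseless twin (exact, per-realization), and
separately check that the analytic model tracks the twin at the
realized-lag granularity.

# Measurement conventions

* Epochs −500..1000 ms; baselines: blink −400..−200 ms (relative to the
  blink maximum), fixation −200..0 ms, saccade −400..−200 ms.
* Peak components are signed extrema of the cluster-mean waveform after
  a ±12-ms moving average — peak scoring on unsmoothed averages is
  noise-biased outward; the smoother's attenuation is deterministic and
  mirrored in the forward model.
* The tonic ERL windows (−400..−200 and −200..−50 ms) coincide with and
  abut the saccade baseline window, so per-channel baselining would
  force the first window to zero identically. Lateralized (contra −
  ipsi) measures are therefore computed from unbaselined epochs: the
  subtraction removes everything common to both hemispheres, including
  baselines and symmetric artifacts. The CNV keeps its explicit
  baseline.
* Lateralized derivations are computed on the *raw* (not IC-cleaned)
  data: ocular ICs are temporally correlated with genuinely lateralized
  pre-saccadic activity, so removing them partially removes the signal
  of interest (classic ICA leakage, reproducible with the generator),
  while symmetric artifacts cancel in the subtraction anyway. For the
  central-cluster measures IC cleaning is optional — on generator data
  the blink artifact carries no weight on the measurement clusters'
  distant sites and a clean-versus-raw comparison is indistinguishable;
  on real data removing ocular components before central-cluster ERP
  analysis remains the recommended path and is what `select_brain()`
  provides.
* Fixation events inherit direction and saccade type from their parent
  saccade; an event's load label is the load of the 10-m segment
  containing its sample.
* Jackknife peak scoring: components are measured on each
  leave-one-subject-out grand average and the ANOVA F is rescaled by
  (n−1)²; for window-mean (linear) measures this equals the conventional
  F exactly, which the tests verify.

# Preprocessing

Band-pass 0.1–40 Hz (zero-phase Butterworth, demeaned first so the DC
step at the record edge cannot ring at a 0.1-Hz cutoff). Robust channel
handling: a channel is corrupt if flat, if the robust z of its SD
exceeds 5, or if its best absolute correlation with any other channel is
below 0.4; corrupt channels are replaced by spherical-spline
interpolation (Perrin-style, order 4) and the data re-referenced to the
average of the good channels, iterated at most four times. ICA training
data are decimated to 250 Hz, high-passed at 1 Hz, cut into 1-s epochs
and screened at 500 µV peak-to-peak; the decomposition is symmetric
FastICA (tanh) on a PCA-compressed rank (non-corrupt channels − 1), and
the unmixing weights transfer to the 0.1-Hz/500-Hz data. Component
classes come from a deterministic heuristic (frontopolar-symmetric
template + burstiness → vertical eye; F7/F8-antisymmetric template +
low-frequency dominance → horizontal eye; spectral slope for brain),
squashed to pseudo-probabilities; components at or below 30% brain
probability are removed for EEG analyses.

# Ocular event detection

Blinks: candidate peaks above median + 4·MAD (polarity auto-calibrated),
Gaussian fits on ±400-ms windows in two passes (the second pass
subtracts neighboring fitted Gaussians so adjacent blinks do not bias
each other); retained iff R² ≥ 0.9 and σ ∈ [25, 150] ms. Saccades:
velocity candidates (local maxima of the smoothed derivative above a
robust threshold) are grouped into three amplitude classes by k-means on
peak-to-peak amplitude (quantile-seeded, deterministic), averaged into
unit-norm templates (an automated monotonicity check replaces visual
inspection), and confirmed where the sliding template correlation
exceeds 0.8. Onset and offset (= fixation onset) are the 10%-of-peak-
velocity crossings measured on the matched template and anchored at the
correlation peak — per-sample crossings are unusable for the smallest
amplitude class under realistic noise. Direction is the sign of the
position change; a saccade is outward if its offset is farther from the
running-median central fixation than its onset.

# Statistics

`rm_anova()` implements the standard within-subject partitioning for one
or two factors with the covariance-based Greenhouse–Geisser epsilon on
orthonormalized effect contrasts; both uncorrected and GG-corrected p
values are always reported. The adjusted partial eta squared is
`df1(F−1)/(df1·F + df2)`, floored at zero (raw value kept as an
attribute). The cluster-based permutation test is one-sample against
zero: cell-wise t maps, two-sided cluster forming at p = .01,
4-connectivity in the frequency × time plane, cluster mass = sum of t,
max-|mass| null over 1000 subject sign-flips, p-values with the +1
convention. Positive and negative clusters are handled separately.

# Numerical choices and problem sizes

* Wavelet cycles rise linearly from 3 (2 Hz) to 8 (30 Hz); band edges
  theta 4–7 Hz, alpha 8–12 Hz. Both configurable.
* The wavelet transform is FFT-based with exact frequency-domain
  decimation: all Morlet kernels live below 45 Hz, so power traces can
  be returned on every 8th sample (62.5 Hz) without any approximation.
  The track-load pipeline also computes only the nine band bins of the
  29-bin grid by default — per-bin z-scoring makes this identical to
  extracting the bins from the full grid, which a test asserts.
* Tercile tie-breaks are stable by segment index; label counts on n
  segments differ by at most one.
* Desk scales used by the test-suite studies, chosen for adequate event
  counts per condition cell rather than by any external constraint: the
  load-recovery study uses 15 subjects × 5-km routes (500 segments, the
  design at 1/10 length); the ERP-recovery study uses 15 subjects ×
  20-km routes (≈150 blinks and ≈250 gaze excursions per subject);
  detection studies use twenty 90-s recordings; the cluster-test
  calibration uses 200 null datasets of 15 subjects × 29 × 150 cells at
  the full 1000 permutations.
* The montage is the standard 32-electrode cap layout (the 30 canonical
  labels plus TP9/TP10). PO7/PO8 are absent from it, so the
  alpha-asymmetry pair defaults to PO9/PO10; the pair is configurable.

# Known limitations

The IC classifier is a deterministic heuristic, not a trained network;
it keeps mixed components whose brain score exceeds 0.30 by design. The
"three expressions" of the saccade-template stage are interpreted as
amplitude classes. Blink-locked baselines overlap long blinks' rise, as
the convention dictates. Single-subject load maps are supported (median
of one) but noticeably noisier than the cross-subject median. All
spatial eye-movement claims are EOG-level; there is no eye tracker in
the loop.
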