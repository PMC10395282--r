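# driveload

Continuous estimation of a driver's mental load from the EEG, and
eye-event-locked analysis of cognitive processing during simulated
driving — for researchers in cognitive neurophysiology, human factors
and driving safety who need markers of attention without experimenter-
controlled stimuli.

## What it computes

**Track-based task load.** The drive is cut into 10-m segments. From a
continuous Morlet wavelet transform (2–30 Hz, 29 linear steps) the
z-scored frontal theta (4–7 Hz; F3, Fz, F4, FC1, FC2) and posterior
alpha (8–12 Hz; P3, Pz, P4, PO9, PO10, O1, Oz, O2) power are segment-
averaged, smoothed over ±50 m, and the per-segment score

    score(segment) = median_subjects( alpha_z − theta_z )

is split into rank terciles: low (alpha-dominant), medium, high
(theta-dominant) task load. Vehicle position is reconstructed by
integrating the transcribed velocity and morphing the distances between
known-position trigger points so that each trigger is hit exactly.

**Eye-event-locked EEG.** Blinks are detected by Gaussian fits on the
vertical ocular IC; saccades by velocity candidates confirmed through
correlation (> 0.8) with three amplitude-class templates, each saccade
labelled left/right and outward/inward. Epochs −500..1000 ms around
blinks, fixation onsets and saccade onsets yield the lambda response
(P1), N1, parietal/occipital P2 and fronto-central N2 per load level
(and saccade type), the pre-saccadic CNV, phasic and tonic event-related
lateralizations (contra − ipsi), saccade-locked ERSPs and the
pre-saccadic alpha asymmetry. Inference: repeated-measures ANOVA with
Greenhouse–Geisser correction and adjusted partial eta squared
(`df1(F−1)/(df1·F+df2)`), jackknife peak scoring with the (n−1)²
F-rescaling, and a one-sample cluster-based permutation test (1000
sign-flip permutations, two-sided cluster-forming p = .01, cluster
significance p = .05).

A synthetic driving-EEG generator (`simulate_route()`,
`simulate_telemetry()`, `simulate_recording()`, `simulate_cohort()`)
produces multi-subject datasets with complete ground truth — route
demand, all ocular events, injected component amplitudes — so the whole
pipeline is testable end to end. See the methods vignette
(`vignettes/driveload-methods.Rmd`) for models, assumptions and design
choices.

## Worked example

```r
library(driveload)

route <- simulate_route(total_distance = 5000, n_triggers = 10, seed = 1)
cohort <- simulate_cohort(route, n_subjects = 3, seed = 1)

tps <- lapply(cohort, function(su)
  trackload_pipeline(su$recording, max_distance = 5000, downsample = 8))
load_map <- assign_task_load(lapply(tps, `[[`, "scores"))
table(load_map$load)
#>   high    low medium
#>    167    166    167

# agreement with the generator's demand terciles
mean(load_map$load == cohort[[1]]$ground_truth$segment_demand$load,
     na.rm = TRUE)
#> [1] 0.844

# blink-locked ERP measures per load level (subject 1, true events)
su <- cohort[[1]]
bset <- epoch_events(su$recording, su$ground_truth$events, "blink")
avg <- grand_average(bset, by = "load")
measure_component(avg, table_components("blink")$N1)[, c("load", "value")]
#>     load      value
#> 1   high -0.3882808
#> 2    low -1.4510204
#> 3 medium -2.0847804
```

Three subjects already place 84% of the 500 segments in the correct
demand tercile. The blink-locked occipital N1 is clearly attenuated at
high load (−0.39 µV) relative to low load (−1.45 µV) — the narrowing of
visual-intake processing under load that the injected amplitudes encode
(low −1.72, medium −1.20, high −0.62 µV). With a single 5-km drive the
medium cell rests on only a dozen blinks and overshoots (−2.08 µV);
the acceptance suite shows that at the 15-subject study scale all
component amplitudes are recovered to within ±0.2 µV.

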