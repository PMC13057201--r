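---
title: "Detecting evoked spine calcium transients and linking them to spine stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting evoked spine calcium transients and linking them to spine stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
library(dplyr)
```

## The problem

Chronic two-photon imaging of dendritic spines combined with optogenetic
stimulation of a presynaptic population makes it possible to ask, synapse by
synapse, whether functional connectivity predicts structural stability. Each
spine's calcium indicator fluorescence is recorded at 30 Hz over repeated
sessions (here five sessions, four days apart) while short light-pulse trains
(3 pulses of 10 ms at 10 Hz, one train every 5 s, 40 trials per session)
drive the presynaptic axons. A spine that receives functional input shows
evoked excitatory postsynaptic calcium transients (EPSCaTs) on a fraction of
trials, set by the synapse's release probability; spines without input from
the stimulated population show none.

`spinedyn` implements the full analysis between extracted ROI fluorescence
traces and the biological conclusions: trial gating, dF/F conversion,
removal of back-propagating dendritic contamination, permutation-null
transient detection, responsive/unresponsive classification, longitudinal
spine-dynamics statistics, spine-volume and path-distance estimation, and
seed-deterministic permutation tests. A synthetic-experiment generator with
full ground truth makes every stage testable without imaging data.

## Detection model

For each ROI and session the pipeline:

1. gates trials: a trial is kept only if its full 1 s pre-stimulus baseline
   is free of motion flags and at least 70% of the stimulation-window frames
   are stable;
2. converts fluorescence to dF/F (per-trial baselines; see
   *Numerical choices*);
3. for spines, removes the dendritic component: spine dF/F is regressed on
   dendrite dF/F with a Huber M-estimator (tuning constant 1.345, at most 50
   IRLS iterations, tolerance 1e-8, slope clipped at zero) and the scaled
   dendrite trace is subtracted;
4. smooths with a 5-bin boxcar and averages the aligned trial windows;
5. builds a permutation null by placing pseudo-onsets uniformly at random on
   motion-free frames of the same processed trace — same pseudo-trial count,
   same window cutting and re-baselining, averaged per shuffle — and takes
   the 95th percentile per aligned timepoint;
6. calls a response when the trial-averaged trace strictly exceeds the null
   threshold in more than 30% of stimulation-window timepoints (50% for
   somatic recordings, which use neuropil correction
   `F = F_raw - 0.7 * F_neuropil` instead of dendritic subtraction).

A spine is **responsive** if a response was detected in at least one session
and **unresponsive** otherwise. Because the criterion demands a run of
significant timepoints rather than a single exceedance, the detector is
conservative: its empirical false-positive rate on null spines is well below
the nominal 5% (see `tests/testthat/test-acceptance.R`).

"More than 95% of the shuffled values" is interpreted per aligned timepoint
of the pseudo-trial-averaged trace, not pooled over time: trial averaging is
explicit in the procedure, so the natural null object is the average trace
under random onsets. Pseudo-onsets are drawn with replacement, excluding
motion-flagged frames and frames too close to the trace edges to fit a
window.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `baseline_frames` | 30 (1 s) | pre-stimulus baseline per trial |
| `stim_frames` | 7 (0.23 s) | pulse train + 1 frame |
| `response_frames` | 15 (0.5 s) | amplitude search beyond the train |
| `n_shuffles` | 10000 | permutation null size |
| `required_fraction` | 0.3 / 0.5 | significant-timepoint criterion (spines, dendrites / neurons) |
| `stable_fraction` | 0.7 | stimulation-window stability threshold |
| neuropil coefficient | 0.7 | somatic neuropil subtraction |
| Huber `k` | 1.345 | robust-regression tuning constant |
| SNR cutoff | 8 | dendrite exclusion, `(p95 - p5) / sd(highpass 10 Hz)` |

## Numerical choices

* **F0 definition.** The source procedure reports dF/F without defining F0.
  Here F0 is the mean of each trial's own 1 s pre-stimulus baseline
  (`compute_dff()`): local, simple, robust to slow bleaching. Inside
  `detect_experiment()` a per-session F0 (mean over all usable baseline
  frames) converts the continuous trace to dF/F scale, and every extracted
  window — real or pseudo — is then re-zeroed on its own baseline mean;
  under mild bleaching this is numerically indistinguishable from per-trial
  ratios and guarantees that real and null windows pass through an
  identical transform.
* **Where the robust regression is fit.** Boxcar smoothing is linear, so it
  commutes with the affine dendritic subtraction; the coupling coefficient
  is therefore estimated on the smoothed traces, where the dendritic events
  stand far out of the noise. Estimating it on raw frames would let
  frame-level noise attenuate the slope (errors-in-variables) while the
  Huber loss downweights the rare event frames that carry the information —
  simulations showed contamination leaking through and inflating the spine
  false-positive rate dramatically. In addition, the coefficient is only
  identifiable when the dendrite is active, so the fit uses frames where the
  smoothed dendrite dF/F exceeds 5 robust standard deviations (at least 15
  such frames, otherwise the coupling is taken as zero — with no dendritic
  activity there is nothing to subtract). `remove_dendritic_component()`
  itself keeps the plain global-fit contract.
* **High-pass filter.** The SNR noise estimate uses a 4th-order zero-phase
  Butterworth high-pass at 10 Hz (order unstated in the source; 4th order is
  a common default). The trace is demeaned first to avoid edge transients.
* **Strictness and ties.** Timepoint comparisons use strict `>`. The
  maximal-dF/F percentile categories cut at the 25/50/75/95th percentiles
  with lower-closed/upper-open intervals; if all values tie, the quantiles
  collapse and every spine is labelled `lowest`.
* **Survival-sequence conventions.** A spine present only in the final
  session is *formed* (it appears and trivially stays to the end). The
  turnover denominator is the mean of the spine counts of the two sessions,
  which keeps the ratio in [0, 2] and symmetric in formation/elimination.
  The survival fraction is normalised to the first-session cohort, so it is
  1 at day 0 and monotone nonincreasing. Lifetime is sessions-present times
  the 4-day interval, cumulative across disjoint runs; the initial
  appearance of a formed or transient spine counts as a state change in the
  flip count.
* **Volume reference pixels.** "The same number of pixels from the closest
  dendrite ROI" is ambiguous about *which* pixels; the N brightest dendrite
  pixels are used — deterministic, and a good proxy for the saturated shaft
  fluorescence that the ratio is meant to normalise by.
* **Degenerate inputs.** Non-positive F0 flags a trial invalid rather than
  dropping it silently; a constant trace is a degenerate-noise error in
  `compute_snr()`; an exact affine spine-dendrite relation short-circuits
  the IRLS (zero scale) to the ordinary least-squares solution; robust-fit
  non-convergence falls back to OLS with a warning.

## The synthetic generator

`generate_experiment()` emulates the experiment's statistical structure with
every random draw derived from one master seed:

* per-trial Bernoulli dendritic events (rate 0.059) convolved with a
  difference-of-exponentials indicator kernel (rise 50 ms, decay 500 ms,
  jGCaMP-like; the source does not report kinetics);
* per-pulse Bernoulli release successes (default probability 0.3, the
  low-release-probability regime of these synapses) with per-spine EPSCaT
  amplitudes coupled to log-normal spine volumes
  (`amplitude = 0.5 * volume + noise`, floored at 0.1 dF/F), giving a weak
  positive volume-amplitude correlation by construction;
* spine traces containing 0.8 of the dendritic signal (so the subtraction
  stage is genuinely exercised) plus their own transients and additive
  noise (sd 0.1 dF/F); dendrite traces carrying a small bleed-through of
  the mean spine signal; mild linear bleaching;
* Poisson-arriving motion epochs (4 per minute, mean 1.5 s) that discard
  roughly 20% of trials under the gating rules, with inflated noise during
  flagged frames;
* presence schedules drawn per longitudinal category (persistent 19.7%,
  transient 45.6%, formed 16.9%, eliminated 17.8%) by enumeration of all
  consistent schedules, so classification round-trips exactly; connected
  spines get triple persistent odds;
* connected spines attached to clustered skeleton nodes (sd 10 µm along the
  dendrite), unconnected spines uniform;
* labelled volume images: a disc whose area is proportional to the true
  volume next to a dendritic shaft, Gaussian-blurred, with Poisson noise.

What it does **not** emulate: pixel-level movies (ROI traces are generated
directly), spontaneous (non-evoked) synaptic activity, indicator
saturation and nonlinearity, slow drift of release probability within a
session, or z-motion artefacts beyond the flagged epochs. Passing tests
therefore validate the statistical machinery under the stated generative
assumptions, not performance on every pathology of real recordings.

## A worked run

A small experiment end to end (sizes reduced for a fast build; the
acceptance script runs the study-scale version: 929 spines on 17 dendrites,
5 sessions, 40 trials, 1000 shuffles):

```{r worked, eval = FALSE}
cfg <- experiment_config(n_spines = 40, n_sessions = 3, seed = 1L)
exp1 <- generate_experiment(cfg)

det <- detect_experiment(exp1, n_shuffles = 1000)
cls <- classify_across_sessions(det)
table(cls$status)

dyn <- dynamics_summary(exp1$ground_truth$presence,
                        status = cls[, c("spine_id", "status")])
autoplot(dyn)
plot_survival_fraction(dyn)

vols <- purrr::map2_dfr(exp1$images, names(exp1$images), \(img, id)
  dplyr::mutate(estimate_volume(img), spine_id = id))
resp <- dplyr::inner_join(dplyr::filter(cls, status == "responsive"),
                          vols, by = "spine_id")
permutation_correlation(resp, volume, max_dff, n_shuffles = 1000, seed = 2)
```

## Known limitations

* Dendritic subtraction assumes a single, well-identified parent dendrite
  trace per spine; multi-branch contamination is not modelled.
* The volume estimator operates on 2D projections; no 3D reconstruction,
  and the pixel-to-µm conversion is a per-image constant.
* Richardson-Lucy deconvolution is provided as an optional pre-step
  (`deconvolve_projection()`, off by default) since the source PSF
  parameters are unknown.
* Mixed models are deliberately delegated to `lmerTest`; the wrapper only
  standardises the contrast table and Bonferroni correction.
* Whether baseline "stability" should also exclude fluorescence drift (as
  opposed to motion only) is an open reading; it is implemented as motion
  only.
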