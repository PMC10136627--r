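---
title: "Microstate-gated connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate-gated connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microconn)
```

## The model

`microconn` analyses event-related potentials (ERPs) under a two-layer
model. The first layer is topographic: at any instant the scalp field is
assumed to be (a scaled copy of) one of a small number of template maps, and
the field switches between templates on a time scale of tens to hundreds of
milliseconds — the microstate model. The second layer is oscillatory: within
the band-limited signal, pairs of channels maintain (or fail to maintain) a
consistent phase relation across trials, quantified by the phase-locking
value (PLV). Gating the PLV by the microstate labels yields one
connectivity network per functional "state" of the epoch rather than a
single epoch-long average, which is the point of the method: transient
network reorganisations are visible only inside their time windows.

Key assumptions, and what breaks when they fail:

* *Piecewise stability.* Back-fitting assigns every sample to some template;
  if the field actually blends templates continuously, labels near
  transitions are arbitrary. We deliberately apply no temporal smoothing or
  minimum-duration rule by default (none is part of the core procedure), so
  segmentations can be fragmented at low SNR; a smoothing pass can be added
  by the user downstream if needed.
* *Polarity carries information.* ERP components are time-locked with fixed
  polarity, so the clustering uses signed spatial correlation throughout: a
  map and its negation are different classes, unlike in resting-state
  microstate work where polarity is folded. All assignment steps
  (clustering, alignment, back-fitting, template matching) share this
  convention.
* *Band-limited phase.* Hilbert-transform phase is meaningful only for
  band-limited signals; PLV is computed on the 0.1–30 Hz output of the
  preprocessing chain (the full analysis band), not on per-band
  decompositions. Narrow bands can be obtained by re-filtering before the
  phase stage.

## Pipeline and parameters

The preprocessing chain is fixed in order — band-pass filter, baseline
correction, amplitude-threshold epoch rejection, average re-referencing,
resampling, per-condition averaging — with per-stage record counts logged.
Parameters that matter:

| parameter | default | why |
|---|---|---|
| band-pass | 0.1–30 Hz | ERP analysis band; zero-phase (forward–backward) 4th-order Butterworth, realised as cascaded high-/low-pass sections because an 0.1 Hz corner inside a band-pass design is numerically fragile. Zero phase protects ERP latencies. |
| epoch window | −200…5000 ms, half-open | stimulus onset at 0 ms, first post-baseline sample; 1300 samples at 250 Hz |
| baseline | −200…0 ms | per-channel mean subtraction |
| rejection threshold | ±100 µV | automatic stand-in for manual artifact screening; it is *not* equivalent to ICA-based cleaning and will not catch structured artifacts (blinks, EMG) that stay under threshold |
| resampling | 250 Hz | Fourier-domain (spectrum truncation), delay-free; polyphase implementations available to us leave an uncompensated group delay, which would bias microstate durations |
| K-means restarts | 20 (5 inside cross-validation) | restarts are cheap insurance against local optima; inside the 50-repeat cross-validation the cost is multiplied by 8 candidate k values, and with k-means++-style seeding 5 restarts were already stable across cohorts |
| convergence | GEV tolerance 1e-6, max 500 iterations | iteration stops earlier when the assignment is stable |
| PLV edge trim | 5% per epoch edge | the analytic signal is distorted at the window edges; trimmed samples are excluded from gated averaging |
| graph mode | weighted, no threshold | PLV matrices are strictly positive, so any binary threshold is a free parameter; weighted Cp uses the geometric-mean triangle form on max-normalised weights, weighted distances are 1/PLV. Binary mode with a threshold is available for comparability with toolbox pipelines. |

## Choosing the number of microstates

Candidate k values (3–10) are compared by split-half cross-validation over
participants: templates fitted on the pooled training-half topographies are
back-fitted to the held-out half and scored by test-set GEV. A subtlety
forces a design decision here: because back-fitting takes the best of k
templates at every sample, test GEV is monotonically non-decreasing in k —
extra templates can win samples but never lose them — so "maximise test
GEV" degenerates to "pick the largest k" whenever the templates are
estimated from ample data. The selection therefore minimises the standard
penalized predictive-residual criterion

$$\mathrm{CV}(k) \;=\; (1 - \mathrm{GEV}_{test})\,
  \Bigl(\tfrac{C-1}{C-1-k}\Bigr)^{2},$$

with C the channel count, which charges each additional template for the
degrees of freedom it consumes. Per-repeat criteria are aggregated by the
median rather than the mean: a single split in which the clustering lands
in a poor local optimum at the true k would otherwise dominate fifty good
ones. Ties go to the smallest k. Raw per-repeat test GEV is returned
alongside, so the monotone curve itself can be inspected.

Two further choices stabilise the selection. Clustering is initialised with
k-means++-style seeding in signed correlation distance (a polarity-flipped
map counts as maximally distant, i.e. as a legitimately distinct class),
which makes degenerate starts rare. And the pipeline clusters the
topographies at local GFP maxima during cross-validation
(`gfp_peaks_only`): GFP peaks are where topographies are quasi-stable and
SNR is highest, they are the conventional clustering set in microstate
work, and they cut the map count roughly six-fold, which is what keeps 50
repeats x 8 candidate k values at desk scale. Full-resolution (all-sample)
clustering remains the default of `kmeans_microstates()` itself and is used
for the final per-participant template fits.

## The synthetic cohort

No public ERP recordings accompany the design this package targets, so the
generator is a first-class module. It emulates the study conditions: 64
channels, a music group of 28 and a control group of 24 participants, 90
trials per participant split evenly over three conditions (negative
picture/negative description; neutral/neutral; negative picture/neutral
description, the reappraisal condition), epochs −200…5000 ms at 250 Hz.
Each condition receives a piecewise-constant template label sequence
(segment lengths uniform on 50–200 ms, consistent with the microstate
literature's tens-to-hundreds-of-ms durations; no immediate repeats), and
each trial renders that sequence as template x smooth positive envelope
plus spatially white Gaussian noise. SNR is defined as the ratio of mean
signal GFP to mean noise GFP — the analysis's own amplitude measure — and
defaults to 5 per trial, the level at which the package's recovery
guarantees are stated. Templates are random second-order spatial
polynomials over a planar electrode layout, resampled until pairwise
|correlation| ≤ 0.5: smooth, dipolar-like, decorrelated enough to be
identifiable yet not orthogonal. Phase coupling is generated by a shared
per-trial oscillator phase plus a per-trial von Mises offset whose
concentration is solved by 1-D root finding so the population mean
resultant length equals the requested PLV.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: volume-conducted forward-model geometry, structured
artifacts (blinks, EMG, drifts), per-participant template variability,
1/f-coloured background EEG, or any coupling between microstate class and
phase coupling strength. Recovery results on synthetic cohorts certify the
pipeline's correctness, not effect sizes in real recordings.

## Numerical conventions and degenerate inputs

* GFP uses the root-mean-square spatial deviation; it is reference-
  invariant and zero only for channel-constant maps (a single channel is an
  error).
* Back-fitting ties keep the previous sample's label when it is among the
  tied classes (temporal smoothness), else the lowest class index —
  deterministic either way.
* Empty K-means classes are reseeded at the currently worst-fit map.
* Class names A, B, … are assigned by descending total labeled time in the
  pooled back-fit; the underlying permutation is returned so maps can be
  re-ordered against any external convention.
* Microstate classes never visited by a segmentation get duration 0 and an
  explicitly flagged empty network (no silent NA propagation into the
  group tables).
* The mixed ANOVA is computed via orthonormal within-subject contrasts and
  Type III hypotheses with sum-to-zero group coding, matching the
  convention of the mainstream statistics packages for unbalanced group
  sizes; Greenhouse–Geisser correction is applied when Mauchly's test
  rejects at 0.05 (both "always" and "never" are available). All-constant
  input is flagged degenerate rather than producing 0/0 statistics.
  Post-hoc comparisons use per-comparison error terms, the common EEG
  convention.
* Zero signals are rejected before phase extraction (their phase is
  undefined); disconnected node pairs (possible only after binary
  thresholding) are excluded from Lp with their count reported.

## Problem sizes

The test suite exercises unit-level properties on 16–24-channel fixtures
and the full scientific checks on a 64-channel cohort of 12 + 12
participants with 50 cross-validation repeats — the cohort size at which
the model-selection check is stated. The null-calibration check runs 2000
simulated cohorts at the full 28/24 group sizes. The complete suite runs in
a few minutes on one CPU.

## Known limitations

* Amplitude-threshold rejection is a stand-in for human/ICA artifact
  screening, not an equivalent.
* Bad-channel interpolation is out of scope; supply clean channels.
* The weighted graph metrics depend on the max-weight normalisation; Cp
  values are comparable within a study but not across datasets with very
  different peak PLV.
* EDF ingestion is not provided; epochs are exchanged as delimited matrix
  files with a JSON sidecar (`write_epochs()` / `read_epochs()`).
* With heterogeneous true template counts across participants the alignment
  step refuses to run (same-k requirement) rather than guessing.
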