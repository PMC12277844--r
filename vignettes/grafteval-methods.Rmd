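---
title: "Quantifying graft integration: models, rules and design choices"
author: "grafteval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying graft integration: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grafteval)
```

## The problem

After a retinal organoid sheet is transplanted into a photoreceptor-degenerated
retina, three questions decide whether the graft is functionally integrated:

1. Do host retinal ganglion cells (RGCs) recover light responses, and of what
   kind (ON, OFF, ON-OFF, low-signal), as a function of distance from the
   graft?
2. How degenerated is the host's interneuron scaffold — here the horizontal
   cell (HC) mosaic, which normally pioneers photoreceptor synapse formation?
3. Do host rod bipolar cells (RBCs) form new ribbon synapses with graft
   photoreceptors?

`grafteval` implements the quantification for all three, together with seeded
synthetic-data generators that stand in for the raw recordings and micrographs
and provide exact ground truth for validation.

## MEA track: flash-response classification

Spike times from a 60-electrode array (30-µm pads, 200-µm pitch) are pooled
into peri-stimulus time histograms with 20-ms bins
(`compute_psth`; the conservation identity
`sum(rates) * bin_width * n_trials = total spikes` holds exactly before
smoothing) and smoothed with an order-4 binomial filter
(`binomial_smooth`; kernel `[1, 4, 6, 4, 1]/16`, symmetric-reflection padding
so constants are fixed points).

The response threshold is `mean + 4 SD` of the dark activity, measured over
10 s of in-trial darkness (`baseline_stats`). Classification rules on the
smoothed PSTH of the reference flash (the strongest intensity, 95.23 R*/rod/s,
2 s long):

* a peak strictly above threshold within 500 ms of light onset → **ON**;
* a peak 50–300 ms after light offset → **OFF**;
* peaks in both windows → **ON-OFF**;
* some window responds but the largest baseline-corrected peak is strictly
  below 10 spikes/s → **LOW_SIGNAL**;
* no window responds → **NOT_CLASSIFIED**.

Window conventions are deliberately sharp so that every boundary case is
testable: the onset window is half-open `(t_on, t_on + 0.5]`, the offset
window closed `[t_off + 0.05, t_off + 0.3]`, a bin belongs to a window if its
center does, threshold comparisons are strict, and peak ties across bins
resolve to the earliest bin.

**Where the SD is measured.** The threshold gates peaks that are read off the
*smoothed* trace, so `analyze_mea` measures the dark mean and SD on the
smoothed PSTH as well. Measuring the SD on unsmoothed bins while thresholding
the smoothed trace would place the cut at roughly
`4 / sqrt(sum(k^2)) ≈ 7.6` smoothed-SDs — so conservative that every
low- and mid-intensity response is censored to zero. `baseline_stats` itself
is agnostic: it computes statistics of whatever PSTH it is handed, so either
convention is available.

### Intensity-response fitting

Baseline-corrected peak rates (subthreshold peaks counted as 0 spikes/s) at
each intensity are fitted with the Naka-Rushton function

$$R(I) = R_{min} + (R_{max} - R_{min})\,\frac{I^n}{I^n + I_{50}^n},$$

with $R_{min}$ and $R_{max}$ fixed to the lowest and largest observed peaks
and $(I_{50}, n)$ minimizing the squared error — a 60×60 log-spaced grid over
$I_{50} \in [\min I/10, \max I \times 10]$, $n \in [0.1, 10]$, refined by
Nelder-Mead on log-parameters (relative tolerance $10^{-12}$). The fitted
curve satisfies $R(I_{50}) = (R_{min}+R_{max})/2$ identically. When all peaks
are equal the fit is flagged degenerate and $I_{50}$, $n$ are `NA`.

Two consequences of fixing $R_{min}/R_{max}$ to observed extremes are worth
knowing. First, noiseless data generated from asymptotic parameters are only
reproduced when the intensity ladder spans the curve's dynamic range (the
observed extremes then nearly equal the asymptotes); recovery to within 1% is
a statement about identifiable truths, not arbitrary ones. Second, the
subthreshold-to-zero rule censors the low-intensity half of shallow curves,
which steepens the apparent curve: on 200 simulated ON cells under the
default conditions the median relative $I_{50}$ error is ≈ 0.3 (reported by
`scripts/acceptance.R` as `median_i50_relative_error`). This is a property of
the published procedure itself, not of the optimizer, whose minimum matches a
500×500 exhaustive grid to within 1%.

### Graft-centric electrode areas

The graft mask is dilated by discs of radius $m \times$ `base_radius` for
magnifications $m = 1, 5, 10, 15$; area 1 is the 1× dilation (graft and
border), areas 2–4 the successive rings, area 5 everything beyond. Dilation
by a disc is evaluated through its exact distance characterization — a point
lies in `mask ⊕ disc(r)` iff its Euclidean distance to the mask is ≤ r — so
electrodes are binned by distance to the nearest graft pixel. This avoids
raster-brush discretization artifacts, makes the nesting
$D_1 \subseteq D_5 \subseteq D_{10} \subseteq D_{15}$ structural, and agrees
with the closed form for disc-shaped masks. The published magnification
factors carry no unit, so `base_radius` defaults to one electrode pitch
(200 µm) and is configurable.

## Horizontal-cell track: mosaic statistics

Counting geometry around the optic disc: for each cardinal direction, three
500-µm sampling circles — proximal, middle, distal — chained by tangency,
the proximal circle tangent to the disc circle (diameter 100–200 µm). Center
distances are therefore `disc_radius + 250/750/1250` µm
(`place_sampling_circles`). Densities divide inclusive point counts
(distance ≤ radius) by the circle area, 0.19635 mm²; damaged circles are
flagged `excluded` by the caller and yield `NA`, never a number.

Nearest-neighbor distances (`nnd`) are exact Euclidean distances to the
nearest other cell, computed without edge correction, with a
relative-frequency histogram (default 5-µm bins over 0–100 µm, extended when
larger distances occur so frequencies always sum to 1). Group comparison uses
the two-sided Mann-Whitney U test (`compare_groups`), exact when tie-free and
the combined n ≤ 16, normal approximation with tie and continuity correction
otherwise.

## Synapse track: the 1.5-µm triple-proximity rule

A synapse is a CtBP2 (ribbon) spot within 1.5 µm — inclusive, "within" read
as ≤ — of both an mGluR6 spot and an RBC dendrite (`detect_synapses`).
Dendrite distance is the exact point-to-segment distance over all polyline
segments, no voxelization; each CtBP2 spot pairs with its nearest partners
(ties to the lexicographically smallest id) and yields at most one record,
preventing double counting in dense neuropil. The dendrite realizing the
shortest distance defines the synapse's RBC.

RBCs are selected when any skeleton point — vertices plus points sampled
every 0.5 µm along segments — lies within 10 µm of the rosette surface
(`select_rbcs_near_rosette`); the surface is a binary mask with anisotropic
voxel support, distances measured to mask voxel centers. Cells with ≥ 1
record are "RBCs with forming synapse"; their count per projected grafted
area (mm²) is the forming-RBC density. `detect_spots` provides a
scale-normalized 3D Laplacian-of-Gaussian blob detector for raster inputs.

## Synthetic generators: what they emulate, and what they do not

All generators draw every random number from one explicitly seeded local RNG
per call; identical inputs and seed give identical output, and the caller's
RNG state is untouched.

**Spike trains** (`gen_spike_trains`): inhomogeneous Poisson processes with
rate `baseline + A_on g(t − t_on) + A_off g(t − t_off)`, `g` a unit-peak
half-cosine bump (default width 0.3 s — chosen for smoothness, compact
support and an unambiguous peak time). Transient amplitudes follow each
cell's Naka-Rushton curve at the trial intensity; ON cells get the onset
bump, OFF the offset bump, ON-OFF both, LOW a small onset bump, NONE none.
Defaults: 16-s trials with the 2-s flash at 2–4 s, dark window 6–16 s, the
recorded ladder 0.83–95.23 R*/rod/s, 20 trials per intensity, baseline
3 spikes/s, `Rmax` 25 spikes/s. LOW cells default to an 8-spikes/s amplitude
ceiling, and need a quiet baseline (≈ 0.5–1 spikes/s) to be expressible at
all: with baseline 3 and 20 trials, 4 SD of the dark bins already exceeds
10 Hz, so no sub-10-Hz peak can clear the threshold — a real interaction of
the published rules, reproduced faithfully. Trials are independent; no
adaptation, no inter-trial correlation, no spike-sorting artifacts.

**HC mosaics** (`gen_hc_pattern`): hard-core dart throwing (rejection cap
10⁴ × N) inside a circular field with the optic-disc circle excluded, then
patchwise independent thinning — emulating the spatially uneven HC loss of
degeneration while leaving the minimum inter-cell distance intact, which is
exactly the published observation (high NNDs become more frequent, the
minimum NND stays put). Defaults: 1000 cells/mm², 15-µm hard core, 1600-µm
field. Real mosaics' density gradients, soma-size variation and imaging
distortions are not modeled, so passing tests demonstrate correctness of the
statistics, not realism of any particular retina.

**Puncta scenes** (`gen_puncta_scene`): planted CtBP2–mGluR6–dendrite
triplets (mGluR6 jittered ≤ 1.4 µm from its CtBP2; a 6-µm dendrite chord
passing 0.5 µm from it) plus distractors of both channels kept
`min_separation` (default 4 µm > 2 × 1.5 µm) from every structure, so planted
triplets always satisfy the rule and distractors never can — giving exact
expected precision and recall of 1. Real confocal effects — anisotropic
blur, spot-detection errors, dendrite tracing gaps — are out of scope.

## Numerical choices and degenerate inputs

* Bins are left-closed, right-open, final bin closed; a spike exactly at the
  trial end is counted.
* Reflection padding duplicates edge bins (symmetric mode); constants are
  exactly invariant under smoothing.
* `peak_response` is never negative; a peak exactly at threshold is 0.
* Histogram relative frequencies sum to 1 by construction (top break closed).
* NND uses direct squared differences per point, not the cross-product
  expansion, so results are bit-identical to a brute-force scan.
* Degenerate IR fits (all peaks equal), empty puncta channels, empty response
  summaries and zero-rate processes all return well-defined empty/flagged
  results rather than errors; infeasible hard-core packing and failed scene
  placement raise bounded-attempt errors.

## Problem sizes

The shipped tests validate against brute-force oracles at desk scale: 200
units × 6 intensities × 20 trials for end-to-end classification, 50 patterns
of 200 points for NND, 20 planted scenes of ~120 spots for synapse detection,
full permutation enumeration up to combined n = 16 for the Mann-Whitney test,
and 500×500 exhaustive grids for the Naka-Rushton optimizer. The full suite
and the acceptance script each run in under a minute on a laptop-class core.

## Limitations

* The classifier reproduces the published rule set; it does not attempt
  latency analysis, receptive-field mapping or spike sorting.
* $I_{50}$ recovery is biased by subthreshold censoring (see above); between-
  condition comparisons remain valid because both conditions share the bias.
* The 10-Hz LOW rule is applied to the baseline-corrected peak and evaluated
  after window detection; the published rule listing leaves both the
  correction and the precedence ambiguous, and both choices are configurable
  in spirit via `grafteval_config`.
* Sampling circles are never excluded automatically; damaged-region exclusion
  is the caller's judgment, as in the original workflow.
* One CtBP2 spot pairs with at most one mGluR6 spot; whether the original
  interactive workflow allowed multiple pairings is not documented.
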