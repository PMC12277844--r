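# grafteval

Quantifying the functional integration of retinal organoid grafts into
degenerated host retinas.

When an organoid-derived photoreceptor sheet is transplanted into a retina
that has lost its photoreceptors (e.g. the *rd1* mouse), three measurements
decide whether the graft works: do host retinal ganglion cells (RGCs) regain
light responses, how degenerated is the host's horizontal-cell (HC) mosaic,
and do host rod bipolar cells (RBCs) form new ribbon synapses with graft
photoreceptors? `grafteval` implements the quantification for all three as
tested, reusable R functions, with seeded synthetic-data generators providing
exact ground truth in place of raw recordings and micrographs. It is written
for retinal physiologists and regenerative-medicine labs running
multielectrode-array (MEA) and confocal quantification pipelines.

## What it computes

**Flash-response classification (MEA).** Spike trains are pooled into 20-ms
peri-stimulus time histograms, smoothed with an order-4 binomial filter
(`[1,4,6,4,1]/16`), and thresholded at the dark-activity mean + 4 SD. A
suprathreshold peak within 500 ms of light onset labels the unit **ON**,
50–300 ms after offset **OFF**, both **ON-OFF**; units whose largest
baseline-corrected peak stays below 10 spikes/s are **Low signal**, the rest
**Not classified**. Corrected peak rates versus flash intensity
(*I*, in photoisomerizations rod⁻¹ s⁻¹) are fitted with the Naka-Rushton
function

    R(I) = Rmin + (Rmax − Rmin) · Iⁿ / (Iⁿ + I50ⁿ)

with `Rmin`/`Rmax` fixed to the lowest/largest observed peaks and `(I50, n)`
minimizing squared error (log-spaced grid + Nelder-Mead refinement).
Electrodes are assigned to graft-centric areas 1–5 by binary dilation of the
graft mask at magnifications 1×, 5×, 10×, 15×.

**HC mosaic statistics.** Cell densities inside 500-µm sampling circles
chained by tangency from the optic disc (proximal/middle/distal × four
cardinal directions), nearest-neighbor-distance (NND) distributions, and
two-sided Mann-Whitney U group comparisons (exact null for small tie-free
samples).

**Host-graft synapse detection.** A synapse is a CtBP2 spot within 1.5 µm of
both an mGluR6 spot and an RBC dendrite (exact point-to-segment distances).
RBCs reaching within 10 µm of the photoreceptor rosette surface are selected;
per-RBC synapse counts and the density of synapse-forming RBCs per grafted
area are reported.

## Worked example

Simulate three RGCs on the recorded flash protocol (2-s flashes,
0.83–95.23 R*/rod/s, 20 trials per intensity), classify them, and fit the
ON cell's intensity-response curve:

```r
library(grafteval)
protocol <- stimulus_protocol()
cells <- list(cell_spec("rgc_on", "ON"), cell_spec("rgc_off", "OFF"),
              cell_spec("rgc_quiet", "NONE"))
ds <- gen_spike_trains(protocol, cells, seed = 42)
res <- analyze_mea(ds, grafteval_config(seed = 42))
res$classes[, c("unit_id", "label", "onset_peak", "offset_peak", "threshold")]
#>     unit_id          label onset_peak offset_peak threshold
#> 1    rgc_on             ON   27.05562     0.00000  9.238671
#> 2   rgc_off            OFF    0.00000    17.67375  8.583560
#> 3 rgc_quiet NOT_CLASSIFIED    0.00000     0.00000  9.124270
```

Each unit is labeled from the smoothed PSTH of the strongest flash; the peaks
are baseline-corrected spikes/s and `threshold` is that unit's dark
mean + 4 SD. The ON cell's intensity-response fit recovers a half-saturation
intensity inside the tested ladder:

```r
fit_intensity_response(subset(res$ir_points, unit_id == "rgc_on",
                              c(intensity, corrected_peak)))
#> Naka-Rushton fit: Rmin = 6.59, Rmax = 27.1 spikes/s, I50 = 7.419 R*/rod/s, n = 1.3 (sse 11.1)
```

Detect planted synapses in a synthetic confocal scene — every planted
triplet is found, no distractor is:

```r
gen <- gen_puncta_scene(scene_spec(n_true_synapses = 5,
                                   n_distractor_ctbp2 = 10,
                                   n_distractor_mglur6 = 10), seed = 42)
rec <- detect_synapses(gen$scene)
head(rec, 3)
#>    ctbp2_id  mglur6_id rbc_id d_ctbp2_mglur6 d_ctbp2_dendrite
#> 1 ctbp2_001 mglur6_001 rbc_01      0.7307951              0.5
#> 2 ctbp2_002 mglur6_002 rbc_02      0.7114126              0.5
#> 3 ctbp2_003 mglur6_003 rbc_03      0.8929503              0.5
```

`run_pipeline(grafteval_config(seed = 1), "out/")` runs all three tracks on a
synthetic demonstration dataset and writes the result tables, a manifest and
a run log. See the methods vignette
(`vignettes/grafteval-methods.Rmd`) for the models, parameter defaults and
design choices.

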