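Package: grafteval
Title: Quantifying Functional Integration of Retinal Organoid Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the integration of transplanted retinal
    organoid sheets into degenerated host retinas. Implements rule-based
    classification of flash-evoked retinal ganglion cell responses from
    multielectrode-array recordings (peri-stimulus time histograms, binomial
    smoothing, mean + 4 SD response thresholds, ON/OFF/ON-OFF/low-signal
    labels), Naka-Rushton intensity-response fitting, graft-centric electrode
    area assignment by morphological dilation, spatial statistics of
    horizontal-cell mosaics (tangent sampling-circle densities,
    nearest-neighbor-distance distributions), and proximity-rule detection of
    host-graft ribbon synapses in three-dimensional puncta data. Seeded
    synthetic-data generators with known ground truth stand in for raw
    recordings and micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
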