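Package: granulyzer
Title: Granule Detection, Classification and Zonal Autofluorescence
    Analysis of RPE Flat Mounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies cytoplasmic granules of retinal pigment epithelium
    (RPE) cells in multi-channel fluorescence z-stacks of flat mounts.
    Detects granules inside manually delineated cell boundaries, classifies
    them into six phenotypes (monolithic and aggregate lipofuscin, round and
    bull's-eye melanolipofuscin, round and spindle melanosomes) from shape
    and 488 nm-excitation autofluorescence features, measures their
    apical-basal zonal dispersion (C1-C4), computes per-cell summary tables
    (count, total area, average size, percent area, mean intensity), counts
    nuclei and scores cell morphology, and runs the group statistics
    (repeated-measures one-way ANOVA with Tukey HSD, paired two-tailed
    t-tests). Includes a ground-truthed synthetic flat-mount generator that
    emulates sodium-iodate dose and time effects so the whole pipeline is
    testable end to end without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
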