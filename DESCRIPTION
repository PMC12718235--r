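Package: hyphalTracks
Title: Dispersal Speed Analysis for Bacteria Tracked on Mycelial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell tracking of bacteria dispersing
    along fungal or oomycete hyphal networks ("fungal highways"). Reads
    TrackMate-style spot tables, computes instantaneous speeds from
    consecutive-frame displacements, applies trajectory- and sample-level
    quality filters, fits truncated continuous distributions and
    two-component mixtures with a uniform background by maximum likelihood,
    ranks candidate models by log-likelihood and information criteria
    (AIC/BIC/HQC), splits pooled speeds into slow and fast regimes at an
    intersection of fitted probability density curves, and compares
    populations with Kolmogorov-Smirnov and Kruskal-Wallis tests. A seeded
    synthetic-trajectory simulator (agents on a branching hyphal network with
    an imaging observation model) makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
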