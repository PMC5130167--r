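Package: vascbranch
Title: Optimal and Constrained-Random Branching Geometry of Vascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether embedded vascular trees branch optimally or
    randomly. Reads Angicart-style vessel tables and SWC morphologies, extracts
    bifurcation junctions, and computes branching angles, sibling asymmetry
    ratios and junction planarity. Implements material-cost (surface-area and
    volume) optimal junction placement as a weighted Fermat problem with a
    complete degeneracy classification, power-cost optimization of Poiseuille
    impedance networks at a single junction and with downstream impedances,
    constrained-random junction resampling at local, intermediate and global
    spatial scales, and statistical comparison of asymmetry distributions via
    moments, kernel density peaks and binned Kullback-Leibler divergence with
    bootstrap p-values. A synthetic tree generator emulating segmented
    angiography output supports end-to-end testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
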