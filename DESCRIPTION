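Package: aggflux
Title: Quantifying Huntingtin-Exon-1 Aggregation Flux in Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A simulation and analysis platform for tracking the flux of
    huntingtin exon 1 (Httex1) molecules between monomer, oligomer and
    inclusion states in transfected neuroblastoma-like cell populations.
    Provides a stochastic hazard-based cell-population simulator, instrument
    simulators for flow-cytometry pulse events, low-speed analytical
    ultracentrifugation radial scans and size-exclusion chromatograms, a
    reproducible quantile-based gating tree (transfection, M/D/L, SYTOX,
    pulse-shape and FlAsH-reactivity gates), population metrics including a
    gated death-rate statistic and expression-binned inclusion kinetics,
    ls-g*(s) sedimentation-coefficient distribution fitting with s20,w
    correction, two-peak chromatogram decomposition, and the combination of
    these assays into a three-class molecular partition of Httex1.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
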