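Package: devnetdyn
Title: Calcium Transient Detection, Network Dynamics Statistics, and a
    Bi-Stable Short-Term-Plasticity Network Model for Developing Hippocampus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing population calcium imaging of densely
    labeled developing neuronal tissue. Implements spatial-template matched
    filtering for somatic calcium transient detection (a spatial analog of
    the Clements-Bekkers sliding-template criterion), a suite of network
    dynamics statistics on binary event rasters (firing irregularity CV2,
    Gini dispersion, network-burst detection with surrogate thresholds,
    continuity classification, Lomb-Scargle spectral power, spike-time
    tiling coefficients, population coupling, and eigendecomposition-based
    motif detection), analysis of pressure-sensor physiology traces, and a
    ten-dimensional Wilson-Cowan-type recurrent network model with
    short-term synaptic depression and facilitation, including fixed-point
    and operating-regime (inhibition-stabilized network) analysis, frozen
    weight approximations, pulse-response experiments, and state-transition
    deadline scans. A synthetic data generator produces ground-truth
    fluorescence movies of overlapping ring-shaped somata and structured
    event rasters so that the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    signal,
    tiff,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
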