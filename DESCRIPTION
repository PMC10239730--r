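Package: dyned
Title: Dynamical Refinement of Continuous-Rotation 3D Electron Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction and structure refinement for continuous-rotation
    three-dimensional electron diffraction (3D ED / MicroED). Implements
    overlapping virtual frames with geometric filtering of partial
    intensities, a Bloch-wave dynamical diffraction engine with numerical
    rocking-curve integration, weighted least-squares refinement of structure
    models against dynamical or kinematical intensities, dual-enantiomorph
    refinement with a binomial z-score statistic for absolute-configuration
    assignment, and difference electrostatic-potential maps for locating
    weak scatterers such as hydrogen atoms. A forward simulator of
    continuous-rotation experiments on synthetic crystals makes the whole
    pipeline testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
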