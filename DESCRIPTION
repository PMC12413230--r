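Package: multipletfit
Title: Multiplet-Aware Fitting of 1D and Pseudo-2D NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative deconvolution of processed 1D and pseudo-2D NMR
    spectra using pseudo-Voigt signal models that encode first-order coupling
    multiplicity. Signals (singlets, doublets, triplets, quadruplets, doublets
    of doublets, and user-defined patterns) are fitted by bounded nonlinear
    least squares (L-BFGS-B, with optional seeded differential-evolution
    refinement), yielding chemical shifts, intensities, areas, coupling
    constants and linewidths with covariance-based standard deviations.
    Includes automated peak picking, parameter initialization from peak lists,
    reference-spectrum batch propagation for time-course (pseudo-2D) series,
    readers for Bruker processed directories and delimited text spectra,
    reproducible session archives, and a synthetic-spectrum benchmark suite
    for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
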