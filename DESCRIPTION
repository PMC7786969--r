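Package: sacchmon
Title: Monitoring Enzymatic Saccharification of Lignocellulosic Particle Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation-free monitoring of the enzymatic saccharification of
    lignocellulosic particle suspensions from time-lapse reactor images and
    low-field NMR relaxometry. Implements gray-level granulometry by
    morphological openings with linear structuring elements (tophat
    preprocessing, pattern spectra, gray-level mean size, size-class
    accounting), exponential saccharification kinetics with half-change times,
    inverse Laplace transformation of CPMG decays into T2 spectra under
    non-negativity and L1 regularization with pore-size calibration, and a
    cross-fraction statistics layer (OLS R2, summary statistics, weighted size
    percentiles and span). A seeded synthetic-data generator produces particle
    image time series under known degradation scenarios, multi-exponential
    CPMG decays, and noisy kinetic series with ground truth, so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
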