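Package: accwave
Title: Statistical Generative Model of Ocular Wavefronts Under Accommodation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling ocular wavefront aberrations measured across
    accommodative demands. Per-eye sets of Zernike coefficients (radial orders
    2-6) measured at six accommodative demands (0-5 dioptres) are mirrored to a
    right-eye convention, rescaled to per-demand standard pupil diameters, and
    reduced to an eigen-wavefront basis by principal component analysis. A
    two-component multivariate Gaussian mixture fitted by expectation-
    maximization on the retained eigenvector scores generates unlimited
    synthetic accommodative wavefronts, and an equivalence-testing battery
    (Kolmogorov-Smirnov normality, TOST equivalence of means, F-tests of
    variances, Bonferroni correction) validates synthetic cohorts against
    their source. Includes a seeded synthetic-population generator emulating a
    young-adult accommodating cohort for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
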