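Package: optimap
Title: Cardiac Optical Mapping Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing dual-dye (voltage and calcium) cardiac
    optical mapping movies and for generating synthetic movies with known
    ground truth.  Computes per-pixel action potential and calcium transient
    metrics (APD80, CaTD80, activation time, 10-90 percent rise time,
    signal-to-noise ratio), segments infarct and remote regions from SNR and
    rise-time criteria, quantifies area-normalized APD dispersion, and models
    sympathetic nerve stimulation and isoproterenol protocols.  Includes exact
    small-sample statistics (Fisher 2x2 enumeration, pooled/Welch t-tests from
    summary statistics, exact Mann-Whitney via a permutation null) and
    percent-positive-area quantification of immunofluorescence images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
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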