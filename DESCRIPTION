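Package: rgclass
Title: Functional Classification of Retinal Ganglion Cell Input to Retinorecipient Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing retinal ganglion cell (RGC) input to different
    retinorecipient brain areas from cell-attached spike recordings and
    retrogradely labeled retinal cell maps. Provides spike-density-function
    estimation, per-cell tuning metrics (normalized vector sum length,
    response duration, size/speed tuning widths and gamma fits, temporal
    cutoff frequency, response polarity), rule-based classification into six
    functional groups, population-proportion statistics, two-dimensional
    Gaussian retinotopy of labeled-cell maps, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
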