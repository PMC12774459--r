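Package: ermquant
Title: Epiretinal Membrane Quantification from SD-OCT B-Scan Detections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds en face epiretinal projection images (EPI) from
    per-B-scan epiretinal membrane (ERM) bounding-box detections on
    spectral-domain OCT volumes, converts the projected region to physical
    area in square micrometres, discretizes a retinal thickness map into
    nine severity classes over the 220-500 micrometre range, and scores
    the association between the ERM region and thickened retina with a
    weighted cumulative intersection-over-union. Also provides the
    observer-study statistics used for clinical validation (correlations,
    quadratic weighted kappa, ICC(2,1), Bland-Altman limits of agreement,
    and acceptability indices) plus a synthetic-scenario generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
biocViews: Software, Visualization, QualityControl
RoxygenNote: 7.3.3
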