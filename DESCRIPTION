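Package: craniosym
Title: Landmark Anthropometry and Symmetric-Template Asymmetry Analysis
    for 3D Craniofacial Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for soft-tissue craniofacial morphometry on triangulated
    head-surface scans. Implements a 14-parameter linear/angular anthropometric
    battery over a closed vocabulary of 37 anatomical landmarks, midsagittal
    canonical-frame estimation from bilateral landmark pairs, a perfectly
    mirror-symmetric parametric head template with thin-plate-spline landmark
    warping and exact closest-point dense correspondence, left-right asymmetry
    scoring with facial/cranial region summaries and heat-map export, cohort
    statistics (two-sample t tests, one-way ANOVA, intraclass correlation for
    inter-rater agreement), and a calibrated synthetic head-cohort generator
    so the full pipeline is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry-utils.R'
    'geometry-io.R'
    'canonical-frame.R'
    'anthropometry.R'
    'tps.R'
    'template.R'
    'asymmetry.R'
    'cohort-stats.R'
    'parameter-tables.R'
    'synthetic-cohort.R'
    'pipeline.R'
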