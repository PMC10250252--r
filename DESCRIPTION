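Package: phantomQCA
Title: Phantom-Based Validation of Coronary Angiography Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating coronary X-ray angiography segmentation
    masks against quantitative coronary analysis (QCA) style references.
    Generates synthetic vascular phantoms (coronary tree with a focal
    stenosis, catheter, and a controlled degraded "prediction" mask),
    measures vessel and catheter diameters along marker lines with
    calibration to millimetres, computes percent diameter stenosis,
    pixel-overlap metrics (accuracy, sensitivity, specificity, PPV, NPV,
    IoU, Dice), aggregates Global Segmentation Score rubrics, and runs
    paired and grouped statistical comparisons between reference and
    segmented measurements, orchestrated as a reproducible study with an
    audit trail.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'caliper.R'
    'geometry.R'
    'gss.R'
    'io.R'
    'overlap.R'
    'phantom.R'
    'pipeline.R'
    'specs.R'
    'stats.R'
    'trees.R'
    'utils.R'
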