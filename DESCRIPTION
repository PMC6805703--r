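Package: triquant
Title: Combined Infarct, Edema and Blood-Brain-Barrier Quantification for
    Rodent Stroke Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies post-stroke injury in a single set of rodent brain
    slices: image-based infarct volume from TTC-stained coronal scans with a
    blue channel-mixer filter that neutralizes Evans blue staining,
    hemispheric edema by the Kaplan ratio, and blood-brain-barrier disruption
    both from blue-stained area on scans and from fluorometric Evans blue
    extravasation with standard-curve calibration, plus a TTC-interference
    assay and the statistical test routing used for group comparisons.
    Includes seeded generators for synthetic slice phantoms and plate data
    with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    nortest,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
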