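Package: octarep
Title: Quantification and Test-Retest Repeatability of OCT Angiography
    En-Face Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify en-face optical coherence tomography
    angiography (OCTA) slabs and assess their test-retest repeatability.
    Implements choriocapillaris flow-void measurement (reference-square
    contrast standardization, projection-artifact suppression via a
    binarized superficial-plexus overlay, translation registration with
    overlap cropping, and an avascular-slab intensity threshold of
    mean + 1.96 SD), vessel density and foveal avascular zone area for the
    superficial and deep capillary plexuses (Otsu global binarization,
    pixel-area summation, manual or seeded automatic FAZ delineation), and
    intravisit agreement statistics (Bland-Altman analysis with the
    coefficient of repeatability, ICC(3,1) with exact F-based confidence
    intervals, and the within-subject coefficient of variation).  A
    synthetic en-face cohort generator with known ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
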