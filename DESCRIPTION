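Package: stiffpdx
Title: Stiffness-Map, Collagen and Expression Quantification for Ovarian Cancer Xenograft Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for shear-wave-elastography studies of
    patient-derived xenograft (PDX) ovarian tumors: ROI statistics and
    replicate averaging of stiffness maps, area-normalized stiffness
    histograms, barycenter radial-gradient analysis, soft/stiff
    classification and stiffness-growth correlation; second-harmonic
    generation collagen fiber morphometry (length, thickness, integrated
    density) and trichrome collagen density via stain color deconvolution
    with H-score support; and a 36-gene-signature molecular subtype
    classifier with compartment-specific differential expression. A
    synthetic phantom generator with full ground truth stands in for the
    animal and patient data, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
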