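Package: quadstitch
Title: Automated Reconstruction of Pseudo Whole-Mount Histology Sections
    from Tissue Quadrants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reassembles a pseudo whole-mount histological section (PWMHS)
    from four digitized tissue-quadrant images by rigid-body registration.
    Quadrants are standardized (down-sampling, flipping, grayscale
    rescaling), tissue masks are segmented, and cut edges are detected from
    minimum-area bounding boxes and Theil-Sen line fits.  A two-component
    cost combining tissue dissimilarity across stitch boundaries (L1
    distance between patch intensity histograms) and boundary misalignment
    (weighted corner-point distances) is minimized by an elitist genetic
    algorithm within a coarse-to-fine resolution hierarchy.  Reconstructions
    are scored against a reference with automatically placed fiducials,
    manually selected fiducials, and the Hausdorff distance between aligned
    convex hulls.  A synthetic phantom generator fragments a pseudo-tissue
    image into quadrants with known ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
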