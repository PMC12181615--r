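Package: cmhq
Title: Detection, Alignment and 3D Quantification of Cerebral
    Microhemorrhages in Stained Serial Brain Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput quantification of cerebral
    microhemorrhages (CMHs) in hematoxylin/DAB-stained serial coronal brain
    sections. Implements optical-density HDAB color deconvolution and YIQ
    chrominance segmentation with Otsu thresholding and particle analysis, a
    random-forest pixel classifier (background/tissue/bleed), batched rigid
    serial-section registration with reference carry-over and a reverse
    refinement pass, 3D volume assembly with surface masking, and whole-brain
    burden metrics (CMH count, area fraction, density per mm2 tissue). A
    synthetic stained-section generator with exact ground truth makes every
    stage verifiable without slide data, and a comparison harness evaluates
    the methods against a reference standard (ANOVA with Dunnett contrasts;
    Kruskal-Wallis with Dunn follow-up for group burden).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    multcomp,
    car,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    graphics,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
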