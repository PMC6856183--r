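Package: octama3d
Title: Rotational 3D OCT-Angiography Analysis of Retinal Microaneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric analysis of retinal microaneurysms in OCT angiography
    (OCTA). Provides a synthetic phantom generator for co-registered OCTA
    flow and structural OCT volumes with layered retina geometry, two
    vascular plexuses and ground-truth lesion ledgers; a depth-sequential
    volumetric projection-artifact removal filter operating on thin
    overlapping subvolumes; en face slab construction, region-of-interest
    placement and microaneurysm candidate detection with cyst exclusion and
    cross-slab deduplication; full 3D grading of each lesion (connected
    vessel branches, plexus origin, retinal layer occupancy, shape class,
    orientation relative to the retinal pigment epithelium, and maximum
    Feret size); and descriptive cohort statistics including Spearman rank
    correlation and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
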