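Package: polrpe
Title: Polarimetric Multimodal Imaging Analysis of Intraretinal RPE Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of intraretinal retinal pigment
    epithelium (RPE) migration in age-related macular degeneration from
    polarimetric multimodal imaging. Simulates co-registered
    polarization-sensitive OCT volumes (two-channel complex speckle fields
    with repeats), polarization-sensitive SLO frame stacks, and
    autofluorescence images of a deformable retina phantom; computes Stokes
    vectors and the degree of polarization uniformity (DOPU) with a 3x3
    kernel and additive-noise correction; builds en-face minimum-DOPU
    projections and depolarized-light images; binarizes B-scans with the
    Shanbhag auto-threshold and measures hyperreflective-focus and pigment
    epithelial detachment volumes (voxel formula and Cavalieri estimator);
    classifies each focus by four-modality concordance with a hard-exudate
    exclusion; and aggregates eyes into cohort tables with chi-square, rank
    and correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    png,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
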