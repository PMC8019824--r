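Package: tractdir
Title: Along-Tract Group Analysis of Principal Diffusion Directions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group analysis of diffusion-tensor principal diffusion
    directions (PDDs) along white-matter fiber bundles. Multi-subject bundle
    masks are intersected, reduced to a one-voxel-wide medial line by
    six-subiteration curve thinning, smoothed with a least-squares B-spline
    and sliced into cross-sectional tract profiles at regular arc-length
    intervals. The axial PDD samples pooled in each slice are modelled with
    Watson and Bingham distributions on the unit sphere; two subject groups
    are compared slice-by-slice through confidence ellipses about the mean
    axis, contiguous runs of significant slices are counted into a weighted
    region-pair difference matrix, and goodness of fit of the directional
    models is assessed with an azimuthal Pearson chi-square test. A seeded
    synthetic-cohort generator (tube-shaped bundles with Bingham-dispersed
    PDDs and a controllable group-difference rotation) supports calibration
    and power experiments without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
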