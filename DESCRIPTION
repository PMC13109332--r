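Package: trayphen
Title: Tray-Prior Calibration and Population Phenotyping for Seedling Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for working with colored point clouds of densely sown rice
    seedlings grown in standard seedling trays: HSV color-space filtering and
    k-nearest-neighbor statistical outlier removal for denoising, restoration
    of metric scale and canonical orientation from the known physical geometry
    of the seedling tray (plane fitting, Rodrigues normal alignment,
    convex-hull long-axis alignment, scale-factor averaging), and extraction
    of population phenotypes (top-fraction plant height, projected canopy
    area, cross-section slab structure, bounding-box, voxel and closed-mesh
    volumes).  Ships the matching, segmentation and regression statistics used
    to evaluate such reconstructions, a deterministic synthetic tray-scene
    generator with full ground truth, PLY input/output for colored clouds and
    triangle meshes, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
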