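Package: choropoint
Title: Topographic Colocalization of Retinal Lesion Point Patterns with
    the Choroidal Vasculature
Version: 0.1.0
Authors@R: person("Choropoint", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the spatial association between marked lesion
    point patterns (e.g. reticular pseudodrusen marked on infrared
    reflectance fundus images) and a binarized choroidal vessel map
    derived from en face OCT C-scans. Provides vessel binarization with
    retinal-vessel exclusion, single-point lesion extraction from marked
    rasters, an exact Euclidean distance transform with distance-binned
    proximity classes (over-vessel, 1-3, 4-6, >=7 pixels), a
    count-matched uniform random-dot null, per-eye summaries, paired
    one-tailed t-tests at the cohort level, scan-geometry calibration
    (pixels to microns), and a fully synthetic eye generator with
    tunable vessel affinity for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
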