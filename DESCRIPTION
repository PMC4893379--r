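Package: cathkin
Title: Objective Endovascular Skill Assessment from Catheter Tip Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for objective assessment of endovascular catheter
    manipulation skill from fluoroscopy-screen recordings of phantom
    cannulation tasks. Includes screen rectification, threshold segmentation
    of the vessel phantom with an exact Euclidean distance-to-wall image,
    brute-force normalized cross-correlation tip tracking, per-stage kinematic
    features (procedure time, path length, average speed and acceleration,
    dimensionless jerk, tip and catheter-shape distance to the vessel wall),
    exact small-sample Mann-Whitney and Wilcoxon signed-rank tests, two-group
    k-means and Gaussian-mixture clustering of experience level and equipment,
    and a synthetic phantom/trajectory generator built from minimum-jerk
    sub-movements with skill-dependent pause, tremor and correction
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
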