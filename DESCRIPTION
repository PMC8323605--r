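Package: msotrack
Title: Multiple Small-Organism Tracking in Time-Lapse Microscopy Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identity-preserving tracking of groups of small aquatic
    organisms (zebrafish larvae, Artemia, Daphnia) in time-lapse microscopy
    video. Segments dark organisms from a mostly static background with an
    adaptive per-pixel Gaussian-mixture model, links detections across
    frames by minimum-cost rectangular assignment (Kuhn-Munkres) with a
    median-distance noise gate, estimates positions of mis-detected or
    occluded organisms by linear interpolation and bridges trajectory
    fragments across short gaps, derives locomotion kinematics (velocity,
    acceleration, heading), and scores tracking output against ground truth
    with the CLEAR MOT metrics (MOTP, MOTA). Includes a synthetic scene
    generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
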