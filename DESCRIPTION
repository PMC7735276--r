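Package: hoptrack
Title: Stereo Videogrammetry and Jump Kinematics for Anuran Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs three-dimensional jump trajectories of anurans from
    two-camera high-speed landmark tracks: flash-based camera synchronization,
    normalized direct-linear-transform camera resectioning with checkerboard
    quality control, homogeneous triangulation, rigid alignment of each hop to
    a standard sagittal plane, and extraction of per-hop kinematic variables
    (mean and maximum velocity, distance, height, take-off and landing angles).
    Includes size-corrected morphometric residual scores, the comparative
    statistics used with them (nested analysis of variance with Type III sums
    of squares, profile-analysis MANOVA of group-by-trait interactions,
    backward-elimination multiple regression, Pearson correlations), raceway
    trial summaries, and a fully ground-truthed synthetic-data generator
    (ballistic hops, simulated stereo rig, cohort presets, raceway trials) so
    that every pipeline stage is verifiable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
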