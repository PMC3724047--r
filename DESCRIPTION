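Package: dmndyn
Title: Dynamic Reorganization of Default-Mode Network Connectivity Across Task States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study task-dependent reorganization of the default-mode
    network (DMN) with seed-based resting-state functional connectivity.
    Implements a synthetic multi-subject, four-state BOLD cohort generator
    with planted region systems and calibrated inter-region correlation
    structure; temporal preprocessing (initial-volume removal, Gaussian
    smoothing, band-pass filtering, nuisance regression, motion scrubbing
    with framewise displacement and global-signal change); seed-based
    whole-brain correlation mapping with Fisher-Z transform and
    Benjamini-Yekutieli FDR control; repeated-measures ANOVA detection and
    classification of voxels into decreasing, increasing and stable systems;
    system-level connectivity dynamics across states; bootstrap
    brain-behavior correlation; and a group spatial ICA validation arm
    (MDL order selection, infomax unmixing, template matching and
    back-reconstruction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
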