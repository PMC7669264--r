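Package: readcircuit
Title: ROI, Peak, Pattern-Reliability and Gradient Analyses of
    Category-Selective fMRI Responses in Beginning Readers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse task-fMRI category-selective responses (words,
    faces, houses) in cohorts of beginning readers, as used in cross-cultural
    studies of reading acquisition and reading difficulty. Implements
    MNI-space sphere ROI construction from literature foci, voxelwise group
    contrasts with permutation cluster-size correction, literature-driven ROI
    univariate analyses with balanced mixed-design ANOVA and
    Benjamini-Hochberg FDR, directional JZS Bayes factors with Cauchy-width
    sensitivity curves, individual activation-peak dispersion analysis,
    split-run multivoxel pattern reliability (MVPA), and anterior-posterior
    gradient profiles of the ventral temporal cortex. A synthetic cohort
    generator emulates the two-language, two-reading-group, two-run design
    under named pathology scenarios (reduced amplitude, spatial dispersion,
    pattern instability) so that every analysis stage can be exercised and
    calibrated without access to the original scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
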