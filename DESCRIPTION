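Package: photoloom
Title: Fiber Photometry and Escape-Behavior Analysis for Looming-Stimulus Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-channel fiber photometry recorded during
    looming-visual-threat assays in mice. Provides isosbestic (405 nm
    reference) artifact correction by least-squares alignment, epoch
    z-scoring, prominence-based transient detection, event-aligned response
    matrices, looming-disk train scheduling and viewing geometry,
    trajectory kinematics with escape / movement-bout / freezing
    segmentation, the statistical layer used in such assays (Pearson
    correlation, paired and pooled t tests, one- and two-way
    repeated-measures ANOVA with Bonferroni pairwise comparisons, 2x2
    chi-squared tests on escape counts), and a synthetic session and cohort
    simulator with full ground truth so every stage is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
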