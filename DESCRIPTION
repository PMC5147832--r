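Package: bloodEWAS
Title: Cell-Type-Resolved Epigenome-Wide Association Analysis of Smoking in Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential DNA methylation analysis of smoking exposure in whole
    blood and purified leukocyte subtypes from 450K-style beta-value matrices.
    Implements robust (Huber) regression of M-values on exposure with
    demographic and leukocyte-composition adjustment, reference-based cell-type
    deconvolution by simplex-constrained least squares, a stratified rank-change
    procedure for smoking-duration effects in heavy smokers, per-cell-type
    effect profiling with hierarchical clustering and response-pattern
    classification, mixture back-projection of cell-type effects to whole
    blood, and a synthetic-cohort generator with planted lineage-specific
    effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, yaml, ape
Suggests: testthat (>= 3.0.0), MASS, withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
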