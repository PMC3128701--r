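Package: anacom
Title: Control-Referenced Voxel-Based Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise lesion-symptom mapping in the AnaCOM style: binary
    lesion masks on a shared standard-space grid are superimposed into a
    maximum overlap map, lesioned voxels are partitioned into subregions by
    identical lesion-coverage pattern, and each sufficiently covered
    subregion is tested against a healthy control sample with a Wilcoxon
    rank-sum test under step-down Holm family-wise correction. Also
    provides scoring of time-based and event-based prospective-memory task
    event logs (ongoing-task accuracy and reaction time, inter-press
    intervals, time-estimation totals, clock checks), a nonparametric
    statistics kernel with exact small-sample tests, and a synthetic
    lesion-and-behaviour cohort generator with ground truth for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
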