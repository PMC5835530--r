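Package: ppnconn
Title: Seed-Based Functional Connectivity of a Multi-Voxel Brainstem Seed
    via Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for seed-based resting-state fMRI functional
    connectivity analysis when the seed is a small multi-voxel region (such
    as the pedunculopontine nucleus) whose effective signal must be learned
    per subject.  Implements temporal preprocessing of extracted time series
    (nuisance regression, polynomial detrending, zero-phase bandpass),
    per-subject NIPALS partial-least-squares decomposition between a
    region-of-interest panel and the seed voxel time courses, cross-subject
    loading tests for candidate-region selection, per-condition
    partial-correlation connectivity profiles with an overall-connectivity
    summary, and group-level stimulation-contrast and severity-correlation
    inference.  Ships a synthetic multi-subject BOLD-like cohort generator
    with known ground truth (planted seed-region couplings, condition
    effects, and a severity link) so that every stage is testable end to end
    without access to subject-level imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
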