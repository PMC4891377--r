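Package: unbiasedfmri
Title: Model-Free Multi-Run fMRI Analysis by Inter-Run Response Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a model-free analysis for task fMRI sessions acquired
    as repeated runs with identical timing. Each voxel is scored by the
    consistency of its time course across runs: ordinary least-squares fits
    between corresponding voxel time courses in all non-identical run pairs
    yield per-voxel beta and t matrices, low-quality runs are excluded
    automatically via iterative one-sided Welch tests on leave-one-run-out
    subject t-maps, and the final result is a reliability map giving the
    percentage of good run pairs in which each voxel exceeds an uncorrected
    p < 0.001 threshold. Also provides a reference single-regressor GLM with a
    canonical double-gamma HRF, R-squared comparison maps and cluster/ROI
    inspection, split-half Dice and circular time-shift evaluation
    experiments, and a synthetic multi-run BOLD simulator with block designs,
    polynomial drift and configurable temporal SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
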