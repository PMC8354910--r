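Package: restmvpa
Title: Cross-Decoding of Resting-State fMRI with Task-Trained Movement Decoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether resting-state fMRI activity contains
    multi-voxel patterns similar to those evoked by discrete movements.
    A regularized logistic regression decoder is trained to discriminate
    wrist from finger movement on block-design task runs, resting scans are
    projected onto the decoder weights to obtain a task-relevancy index (RI),
    and the spread of the RI series is compared against an empirical null
    built from iterative amplitude-adjusted Fourier transform (IAAFT)
    surrogates of the weight vector.  Includes temporal preprocessing
    (nuisance regression, detrending, band-pass filtering), leave-one-session-out
    cross-validation, a synthetic-data generator with known ground-truth
    patterns for validation, and an end-to-end experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    RNifti,
    withr
Config/testthat/edition: 3
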