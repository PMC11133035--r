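Package: revcorrcs
Title: Compressive Sensing for Reverse Correlation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers latent perceptual templates (classification images) from
    binary yes/no responses to random visual noise, both by conventional
    reverse correlation and by a closed-form one-bit compressive-sensing
    estimator that recovers a sparse representation of the template in the
    orthonormal two-dimensional discrete cosine basis from far fewer trials.
    Includes a simulated-observer framework (ideal and noisy observers), an
    L1-penalized logistic-regression comparator fit by proximal gradient
    descent, reconstruction-quality metrics (template r-squared, balanced
    response-prediction accuracy), k-fold cross-validated response prediction,
    sparsity-level selection by held-out prediction accuracy or nested
    cross-validation, and scripted replication of the simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
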