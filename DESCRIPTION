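Package: connlsm
Title: Connectome-Based Lesion-Symptom Mapping with Sparse Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating structural-connectome disruption to
    behavioural deficits in lesioned cohorts. Implements sparse partial
    least squares (sPLS1) regression with soft-thresholded weights,
    variable importance in projection (VIP) scoring, bootstrap-VIP
    stability selection, nested-model held-out evaluation, and a
    synthetic stroke-cohort generator that emulates spatially
    correlated edge disruption from contiguous lesions. Includes the
    feature-space construction rules used in connectome studies:
    volume-normalised edge weights, lower-triangle vectorisation,
    mean-connectivity thresholding and forced inclusion of
    superior-longitudinal-fasciculus edge groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
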