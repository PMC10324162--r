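Package: kpembed
Title: Kernel-Preserving Embedding of Drug-Target Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects drugs and protein targets into a single low-dimensional
    Euclidean space such that Gaussian kernel values between embedded points
    reproduce known drug-target interaction scores and within-domain
    (drug-drug chemical, target-target genomic) similarity scores. Each
    coordinate block is constrained to a Stiefel manifold and fitted by
    alternating limited-memory Riemannian BFGS (or steepest descent with
    Armijo line search). Includes out-of-sample embedding of unseen drugs
    from their similarity profiles, drug-wise cross-validation with
    AUROC/AUPRC, Euclidean-distance ranking of novel interactions, a
    synthetic network generator with planted low-dimensional geometry,
    readers and writers for labeled tab-delimited matrices, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
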