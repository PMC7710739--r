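Package: immunodyn
Title: Longitudinal Tumor Immune Dynamics from Serial Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for serial tumor biopsy cohorts profiled across
    neoadjuvant treatment time points. Implements random-intercept linear
    mixed-model differential expression with likelihood-ratio testing,
    single-sample gene-set scoring (kernel-ECDF random-walk enrichment),
    cytolytic activity scoring, nu-support-vector-regression immune cell
    deconvolution, integrative latent-variable clustering of immune states
    with transition bookkeeping, non-negative matrix factorization based
    virtual microdissection with entropy-scored exemplar genes, digital
    H&E-style lymphocyte detection and TIL density estimation, and
    elastic-net bootstrap outcome association. Ships a synthetic cohort
    generator with retained ground truth so every stage is testable
    end-to-end without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
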