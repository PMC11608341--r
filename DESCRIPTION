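Package: omicreml
Title: Multi-Omics Variance Components via GREML and CORE-GREML with
    Exposome Mediation
Version: 0.1.0
Authors@R:
    person("Omicreml", "Developers", email = "omicreml@example.org",
           role = c("aut", "cre"))
Description: Integrative variance-partitioning of an ordinal disease
    phenotype across omics layers (genome, transcriptome, metabolome,
    exposome). Builds genomic and feature-based relationship kernels with
    quality control and relatedness pruning, estimates additive,
    interaction (Hadamard) and covariance (CORE-GREML) variance
    components by average-information REML, performs boundary-corrected
    likelihood-ratio tests and GREML power calculations, and quantifies
    exposome mediation of omics effects through cross-validated BLUP risk
    scores with bootstrap confidence intervals. Includes a synthetic
    multi-omics generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
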