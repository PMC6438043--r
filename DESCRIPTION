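Package: paritysig
Title: Parity-Associated Gene-Expression Signatures in Normal Breast Tissue
Version: 0.1.0
Authors@R: person("paritysig", "maintainers", email = "paritysig@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting parity-associated
    gene-expression signatures in normal breast tissue from probe-level
    microarray data: present-call and coefficient-of-variation probe
    filtering, parametric empirical-Bayes (ComBat-style) batch adjustment,
    replicate concordance QC (Lin's CCC), per-probe regression with Storey
    q-value FDR control, stratified discovery/validation resampling
    selection, time-since-last-pregnancy (TSLP) fold-change profiling with
    K-means clustering under the uncentered-Pearson distance, temporal
    pattern classification (transient / long-term changing / long-term
    constant and the two downregulated patterns), conditional
    hypergeometric GO enrichment with broad-category rollups, whole-tissue
    linear decomposition into epithelium and stroma, and RT-PCR
    delta-delta-Ct concordance statistics. Includes a synthetic-data
    generator emulating the cohort's statistical structure so every stage
    is testable without any download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
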