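Package: lomnet
Title: Longitudinal Multi-Omic Variance Decomposition and Cluster-Level
    Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for small longitudinal multi-omic studies of
    the kind used in non-human-primate drug-administration experiments:
    median-of-ratios normalization and log2 transformation of RNA-seq count
    matrices, technical-replicate collapsing and quality filtering of LC-MS
    metabolite feature tables, principal-component variance-component
    decomposition attributing variance to animal and timepoint, cross-omic
    principal-component correlation screening, blood-informative-transcript
    axis scoring, per-feature ANOVA with false-discovery-rate control and a
    paired consistent-response test, pathway-level PC1 summarization with
    Ward clustering, and quality-threshold clustering followed by
    mutual-information-preserving discretization, Sparse Candidate Bayesian
    network structure learning, and subsample/shuffle edge-robustness
    estimation. Includes a synthetic-data generator emulating a
    five-animal, seven-timepoint, two-compartment design with planted
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
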