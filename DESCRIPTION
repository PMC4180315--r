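Package: methylICC
Title: Reliability of Array-Based DNA Methylation Measurements from
    Technical Replicates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the reliability of Infinium-style DNA methylation
    beta values using technical replicates. Estimates a per-CpG intraclass
    correlation coefficient (ICC) from a one-way random-effects ANOVA,
    models the genome-wide ICC distribution as a censored- or
    truncated-normal mixture fitted by an EM algorithm, classifies probes
    into zero-, low- and high-reliability clusters by posterior
    probability, and demonstrates the downstream impact on an
    epigenome-wide association study with chip random effects, including
    the Bonferroni power gain from excluding unreliable probes. A
    synthetic-study generator reproduces the replicate/chip design the
    method assumes so the whole pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, QualityControl, Epigenetics, MethylationArray,
    BatchEffect
RoxygenNote: 7.3.3
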