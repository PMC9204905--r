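Package: methfunnel
Title: Methylation Biomarker Screening, qPCR Quantification, and
    Circulating-DNA Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for promoter-hypermethylation biomarker
    discovery and monitoring in breast cancer. Implements a five-criterion
    genome-wide screening funnel that nominates hypermethylated,
    expression-silenced genes associated with poor hormone-therapy response;
    relative quantification for methylation-specific and reverse-transcription
    qPCR with twofold/half-fold calling rules; circulating methylated-DNA
    trajectory classification benchmarked against serum CEA and CA15-3;
    diagnostic evaluation (confusion metrics, ROC/AUC, Fisher's exact,
    chi-squared, Mann-Whitney, Spearman); and Kaplan-Meier, log-rank and Cox
    survival analysis. A synthetic-cohort generator reproduces the statistical
    structure of the study inputs so every stage is testable without
    restricted patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
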