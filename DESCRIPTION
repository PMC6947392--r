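Package: methbrush
Title: Targeted Bisulfite Amplicon Methylation Scoring and Survival
    Analysis for Oral Brushing Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for 13-gene oral-brushing DNA methylation
    prognostics: simulation of targeted bisulfite amplicon panels, reads and
    clinical cohorts; native per-CpG methylation-ratio calling from FASTQ
    (quality filtering, in-silico converted-reference assignment, coverage
    gated ratio estimation); a linear-discriminant CpG score with ROC-based
    CpG ranking and Youden threshold selection, including the published
    fixed positivity threshold; and cohort survival statistics
    (Kaplan-Meier, log-rank, Cox proportional hazards with Efron ties and
    bidirectional stepwise selection, Schoenfeld proportionality test).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
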