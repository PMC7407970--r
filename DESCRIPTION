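Package: mirmaster
Title: miRNA Master Regulator Discovery from Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("mirmaster", "developers", email = "mirmaster@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering miRNA master regulators
    from paired miRNA/mRNA count matrices: negative-binomial differential
    expression with Benjamini-Hochberg correction, selection of miRNAs
    consistently upregulated across clinical stages (Spearman stage
    correlation), ARACNe-style mutual-information network inference with
    data-processing-inequality pruning and bootstrap consensus, target
    database filtering, MARINa-style master regulator calls via normalized
    enrichment scores, an Oncogenic Activity score that balances regulated
    oncogenes against tumor suppressors, and median-split survival analysis
    (Kaplan-Meier, log-rank, Cox regression). Includes a seeded synthetic
    cohort generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
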