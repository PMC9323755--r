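Package: omicsmr
Title: Summary-Statistics Multi-Omics Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing likely causal genes for a quantitative
    trait from GWAS, cis-eQTL and cis-mQTL summary statistics. Implements the
    summary-data-based Mendelian randomization (SMR) ratio test with the HEIDI
    heterogeneity filter, a MetaXcan-style summary transcriptome-wide
    association statistic with ridge-trained prediction weights and an
    approximate-Bayes-factor colocalization screen, a three-way SMR mediation
    analysis linking DNA methylation to gene expression to the trait,
    tissue prioritization by average squared Z, multi-source evidence scoring,
    and Fisher's exact drug-target enrichment. Ships a synthetic-data
    generator with planted causal architectures (chain, direct, pleiotropy,
    linkage, null) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
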