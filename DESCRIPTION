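Package: nc886proxy
Title: Genotype-by-Epigenotype Proxy for Lifelong nc886 RNA Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the polymorphically imprinted nc886 (vtRNA2-1) locus
    from DNA-methylation beta values, infers the parental origin of the
    rs1799962 minor allele from family trios, combines epigenotype and
    genotype into a proxy for lifelong nc886 RNA levels, and associates the
    proxy with cardiometabolic phenotypes per cohort and by fixed- or
    random-effects meta-analysis. Includes a synthetic-cohort generator
    encoding the locus' regulatory model (maternal-allele silencing,
    cis-acting minor-allele effect) so the full pipeline is testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    mclust,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
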