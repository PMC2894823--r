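Package: cnvrkit
Title: Copy-Number Variable Region Detection and Genome-Wide Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copy-number variable regions (sub-CNVRs) from per-subject
    CNV calls with a sweep-line counter algorithm, optionally merges consecutive
    sub-CNVRs and assigns per-subject copy-number states, and tests each region
    against quantitative phenotypes by covariate-adjusted multiple linear
    regression with Student-t p-values and Bonferroni genome-wide significance.
    Includes readers and writers for CNV call tables (generic CSV and a
    segment-summary dialect), phenotype and genotype tables, Manhattan and
    region-distribution plots with machine-readable sidecars, a synthetic-data
    generator with planted effects for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
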