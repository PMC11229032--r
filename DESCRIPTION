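Package: cartarget
Title: Expression-Based Discovery and Assessment of CAR Therapy Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Batch toolkit for identifying and evaluating candidate antigens
    for chimeric antigen receptor (CAR) cell therapies from bulk RNA-seq
    expression. Loads TCGA/GTEx-shaped tumor and normal-tissue TPM matrices
    and DepMap-shaped cancer cell line expression, restricts the search to
    plasma-membrane (surfaceome) genes, screens for tumor-associated
    antigens by median fold change with Mann-Whitney U tests and
    Benjamini-Hochberg correction, profiles off-tumor expression across
    healthy tissues, scores dual-antigen logic gates (AND/OR/NOT/IF-BETTER)
    by expression coverage, and selects cancer cell lines by target
    expression threshold. Includes a reproducible synthetic cohort
    generator with planted fold changes and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
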