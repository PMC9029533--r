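Package: gemtx
Title: Transcriptome-Constrained Genome-Scale Metabolic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene-expression measurements into genome-scale
    metabolic models. Classifies genes as expressed or suppressed under
    global and local thresholding schemes, maps expression onto reactions
    through gene-protein-reaction (GPR) Boolean rules, builds
    context-specific models under several constraining strategies, and
    analyses them with flux balance analysis (FBA) and flux variability
    analysis (FVA): high/low expression filters, cross-phenotype
    comparison, non-flux reactions, rate-limiting reactions and flux
    shifts. Reads SBML Level 3 (FBC), JSON and tabular models, CSV or
    spreadsheet transcriptomes and medium-composition tables, and writes
    all results as report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
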