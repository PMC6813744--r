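Package: steatox
Title: Cross-System Toxicogenomic Analysis of Steatogenic Chemical Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cross-system (rat in vivo, rat in vitro,
    human in vitro) toxicogenomic analysis of liver-steatosis-inducing
    chemical exposures. Implements rank-product differential expression with
    permutation-based percentage-of-false-prediction (pfp) estimation,
    hypergeometric pathway over-representation with Benjamini-Hochberg
    adjustment, transcription-factor (molecular initiating event) target
    activation scoring, metabolite-level predictions from genome-scale
    metabolic networks by weighted flux minimization (TIMBR), and
    parallelogram overlap analysis of genes, pathways, and metabolites across
    test systems. Ships a synthetic-data generator with planted ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
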