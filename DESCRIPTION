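Package: revscreen
Title: Signature-Reversal Screening for Transcriptomic Agent Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reverse-transcriptomics screening tools: extraction of
    fold-change gene signatures from case/control contrasts, anti-correlation
    scoring of candidate agents against a disease signature (Fisher's exact
    odds ratio on the signed signature overlap together with Spearman
    correlation of the fold-change profiles), deterministic agent ranking,
    treatment-reversal validation, differentially-expressed-gene extraction,
    hypergeometric over-representation analysis against GMT gene-set
    collections, and a synthetic-data generator with planted ground truth
    (differential expression, reverser/mimicker/null agents, enriched gene
    sets) for end-to-end validation of the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
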