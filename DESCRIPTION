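Package: pvstrat
Title: Stratification Decisions for Spontaneous-Report Signal Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decide whether a drug class (for example Traditional Chinese
    Medicine) should be analysed separately in pharmacovigilance signal
    detection. Ingests spontaneous adverse drug reaction (ADR) reports,
    runs four disproportionality methods (PRR, ROR, MHRA criteria, BCPNN
    information component) on the full database and on a drug-class
    stratum, compares both detection runs against a reference database of
    known drug-ADR associations through a known/unknown-split fourfold
    table, computes recall, precision and discrepancy indicators, and
    applies a decision tree that returns a separation or non-separation
    verdict. Includes a seeded simulator for multi-stratum spontaneous
    reporting systems with planted signals, and the fourfold tables of a
    published nationwide worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
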