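Package: icdcoder
Title: Rule-Based Semi-Automatic ICD-10 Diagnosis Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A regular-expression rule engine for assigning ICD-10 (and
    CCD-style extension) diagnosis codes to free-text diagnosis
    descriptions. Provides parsing and validation of one-rule-per-code
    rule bases, deterministic batch matching with unique-match assignment
    and failure logging, audit classification of coding outcomes against
    gold codes, precision/recall/F-measure/accuracy evaluation,
    code-frequency and chapter analytics, and a seedable synthetic-corpus
    generator so the whole pipeline can be exercised without hospital
    data. A command-line front end exposes validate, code, evaluate,
    report and simulate commands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
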