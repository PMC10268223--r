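Package: icuharm
Title: Harmonization of Heterogeneous ICU Electronic Health Record Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A concept-dictionary approach to intensive-care EHR data
    harmonization. Declarative JSON source configurations describe a
    database's tables, identifier systems and timestamp conventions;
    a dictionary of clinical concepts (vitals, labs, medications,
    outcomes, and recursive scores such as SOFA and Sepsis-3) maps
    per-source extraction rules onto uniform id-keyed, time-stamped or
    windowed tables. Includes time-series verbs (binning, aggregation,
    gap filling, LOCF imputation, window expansion, sliding windows,
    identifier-system conversion), a 119-concept clinical dictionary,
    and a synthetic cohort generator that renders one ground-truth
    cohort into three schema dialects (long entity-attribute-value with
    absolute times and nested identifiers, wide periodic with relative
    times, long with relative times) so the whole pipeline is testable
    without credentialed data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
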