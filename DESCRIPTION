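Package: claimsbirth
Title: Validation of Claims-Based Childbirth Identification Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating claims-based phenotyping
    algorithms that identify the month and year of childbirth in
    administrative claims databases. Provides ICD-10 category code-set
    handling, 32 built-in Boolean code-combination algorithms over
    diagnosis (with or without a suspected flag), procedure and medication
    domains, a parent-child-linkage gold standard with age and
    husband-identifiability filters, month-tolerant event matching,
    sensitivity/specificity/PPV/NPV/kappa/Youden metrics with confidence
    intervals, a washout-window scan for second births, and a synthetic
    claims-data generator with known ground truth for method testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
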