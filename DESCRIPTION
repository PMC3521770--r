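Package: seropanel
Title: Design and Validation of Autoantibody ELISA Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for triaging candidate tumour-associated antigens and
    extending OR-rule autoantibody ELISA panels. Screens antigens for
    cancer/control discrimination with the two-sample Kolmogorov-Smirnov
    distance, optimizes per-antigen optical-density cut-offs singly and
    jointly across a panel (coordinate ascent with random restarts, or
    exhaustive search), quantifies the additive contribution of candidate
    leads to an existing panel, scans lead combinations, validates frozen
    cut-offs on an independent cohort, and converts sensitivity and
    specificity into positive predictive value at a stated prevalence.
    Includes a synthetic-cohort generator emulating matched case-control
    ELISA studies with seropositive mixture signals and titration curves,
    so the whole pipeline runs and is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
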