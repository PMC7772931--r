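Package: recoverysem
Title: Structural Equation Models of Addiction Recovery and Relapse from Social-Media Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying addiction recovery and relapse from the
    posts of drug users on community forums. Post text is scored against
    psycholinguistic category lexicons (LIWC-style dictionaries with exact
    terms and stem wildcards), user timelines across recreational-drug-use
    and recovery forums are filtered and labeled for recovery and relapse,
    and the resulting per-user feature matrices are analysed with a native
    structural equation modeling engine: maximum-likelihood covariance
    fitting over a reticular (RAM) parameterization, asymptotic standard
    errors, standardized solutions, and the CFI, TLI, RMSEA and SRMR fit
    indices with conventional threshold labels. A seeded synthetic-data
    module generates factor-structured features, category-bearing post text
    and event-structured timelines with known ground truth so the whole
    pipeline is testable without access to platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
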