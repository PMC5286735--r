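Package: lcasub
Title: Latent Class Subgrouping of Multi-Domain Patient Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-mixture latent class analysis for mixed nominal, ordinal
    and continuous indicators under local independence, estimated by EM with a
    missing-data-tolerant likelihood. Implements the model-generation workflow
    used in questionnaire-based patient subgrouping: class counts searched from
    one upward with seeded random restarts and a most-consistent-BIC retention
    rule, a one-percent BIC-decrease rule for choosing a starting model, a
    two-stage pipeline that first fits one latent class model per health domain
    and then clusters the modal domain memberships, and a diagnostics toolkit
    (posterior-certainty summaries, normalized severity profiles, feature
    detection, subgroup-size checks and flagged membership cross-tabulations).
    A synthetic-cohort generator with planted latent structure emulates a
    multi-domain low back pain questionnaire study so that every pipeline stage
    is testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
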