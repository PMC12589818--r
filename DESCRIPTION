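Package: psqa
Title: Patient-Specific QA Analytics with TG-218 Limits and Process Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for centralized analysis of patient-specific quality
    assurance (PSQA) records from intensity-modulated radiotherapy
    verification. Provides validated CSV ingestion with controlled
    vocabularies, disease-site normalization, TG-218-style tolerance width
    and action/tolerance limit derivation per disease site and facility,
    individuals/moving-range statistical process control charts,
    interquartile-range outlier flagging with limit-breach alerting, a
    multi-facility synthetic cohort generator with anomaly injection for
    method validation, and an end-to-end stratified reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
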