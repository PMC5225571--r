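Package: comorbidARM
Title: Matched Case-Control Comorbidity Analysis with Association Rule Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comorbidity pattern analysis in claims-like diagnosis
    records, built around the borderline personality disorder comorbidity
    study design: a synthetic claims generator with configurable category
    prevalences and case-vs-control odds ratios, ICD-9-CM category mapping,
    incident-case selection with 1:4 exact age- and sex-matched controls,
    2x2 odds ratios with Wald confidence intervals, lift-ranked top-k
    association rule mining in the zero-minimum-support regime, train/test
    rule validation, and a matched bootstrap that resamples cases and
    re-matches controls to aggregate rule metrics over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
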