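Package: alcsms
Title: Tailored Web- and SMS-Based Alcohol Intervention Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the computational core of a tailored web- and text
    messaging-based program to reduce problem drinking in young adults:
    screening and baseline assessment instruments with validation, a
    three-tier drinking risk classifier, age- and gender-specific normative
    feedback (consumption percentile, drinking costs, calories, blood
    alcohol concentration), a 12-week tailored SMS schedule with template
    rendering and unsubscribe handling, a synthetic cohort simulator with
    class clustering and configurable pre-post effects, generalized
    estimating equations with cluster-robust (sandwich) variance for the
    pre-post evaluation, and participant-flow and program-use reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
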