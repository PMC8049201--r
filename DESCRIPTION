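Package: gpcomplexity
Title: A Consultation-Complexity Measure for General-Practice Electronic Records
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to build and apply a binary measure of general-practice
    consultation complexity from routine coded primary-care records. Implements
    two-round Delphi consensus scoring of candidate complexity factors,
    clinical code-set based flagging of consultation-level and patient-level
    factors with lookback windows, the measure-development pipeline (prevalence
    screening, percentile-based threshold respecification, mixed-effects
    validation of each factor against consultation duration with random
    intercepts for practice and patient, and backward stepwise elimination),
    and summary reporting of the final measure. A synthetic primary-care data
    generator with known ground truth makes every stage testable without
    access to licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
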