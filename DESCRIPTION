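Package: iccmcea
Title: Markov Cohort Cost-Effectiveness Model of Promoting Community Case
    Management of Under-5 Pneumonia
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model (well, moderate pneumonia,
    severe pneumonia, dead) evaluating the cost-effectiveness of promoting
    integrated community case management (iCCM) of childhood pneumonia
    through proprietary and patent medicine vendors in Nigeria.  Provides
    parameter handling with distribution fitting from published means and
    95% intervals, an itemised promotion cost ledger with capital
    annualisation, the cohort engine with half-cycle correction, DALY
    (YLD/YLL) accounting, incremental cost-effectiveness analysis with
    probabilistic and deterministic sensitivity analysis, a
    microsimulation oracle, and a structural-option calibration harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
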