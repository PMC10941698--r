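Package: contrasim
Title: Individual-Based Microsimulation of Contraception, Pregnancy and
    Family-Planning Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time individual-based simulation of contraceptive
    method use and pregnancy for women of reproductive age. Women move
    monthly between eleven contraception states (initiation, switching,
    discontinuation, method failure), become pregnant, give birth after a
    nine-month scheduled event, and may start a method postpartum.
    Family-planning scale-up interventions act as multipliers on initiation
    probabilities. The package includes calibration routines (age-specific
    pregnancy scaling factors, secular trends in starting/stopping
    contraception, intervention multipliers fitted to target method mix),
    consumable-package costing with currency conversion and
    population-scaled implementation costs, reporting utilities (method
    mix, pregnancy proportions, population pyramids, dependency ratio,
    national scaling), and a synthetic month-by-month contraceptive
    calendar generator with an occurrence-exposure estimator for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
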