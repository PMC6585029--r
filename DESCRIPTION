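Package: netdaly
Title: Net Human Health Effect of a Health Care Pathway: Patient Benefit
    and Environmental Burden in DALYs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines a monthly-cycle Markov cohort model of schizophrenia
    maintenance treatment (long-acting paliperidone palmitate injections
    versus treatment interruption) with a life-cycle environmental burden
    assessment of the care pathway. The cohort model, built with dwell-time
    tunnel states for relapse, yields Years Lived with Disability, Years of
    Life Lost, DALYs and QALYs together with the health-care consumption
    profile (syringes, visits, bed days). Per-unit endpoint factors convert
    that consumption into environmental Human Health DALYs, and both sides
    are merged into a net DALY score with one-way and probabilistic
    sensitivity analysis over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
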