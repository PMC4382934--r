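Package: rxperiods
Title: Drug Use Periods from Prescription Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs continuous drug use (exposure) periods with estimated
    average daily doses from per-person prescription-purchase histories, as
    recorded in pharmacy dispensing registers. Implements a second-generation
    exposure-modelling procedure built on sliding weighted temporal dose
    averages (DDD per day), purchase-regularity statistics, package
    refill-length distributions learned from the data, a three-level expert
    parameter hierarchy (global, ATC class, drug package), and a
    stockpiling-aware decision walk that joins consecutive purchases into
    treatment episodes while accounting for hospital stays. Includes a
    synthetic-cohort generator with known ground truth for validating every
    step without access to register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
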