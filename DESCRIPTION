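Package: adcscale
Title: Interspecies Allometric Scaling of Antibody-Drug Conjugate Clearance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts human clearance of antibody-drug conjugates (ADCs)
    from animal pharmacokinetic data by interspecies allometric scaling.
    Fits the power law CL = a*W^b to multi-species clearance panels,
    applies the Rule of Exponents with maximum-life-span-potential and
    brain-weight correction factors, and supports one-, two- and
    three-species scaling strategies. Includes a bundled multi-species
    ADC clearance dataset, prediction-ratio evaluation against observed
    human clearance, a lognormal synthetic-data generator with
    parameter-recovery experiments, and reproduction reports for the
    published reference analysis.
License: MIT
Encoding: UTF-8
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
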