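Package: micdad
Title: Misclassification of Disease Status at Death in Illness-Death Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for quantifying the bias that misclassification
    of disease status at death (MicDaD) induces in mortality rate ratio (MRR)
    estimates for chronic conditions. Provides age-dependent Gompertz-type
    transition intensities for a three-state illness-death model, a vectorised
    discrete-event simulator of birth-cohort life courses, survey-based masking
    of post-participation diagnoses, person-time splitting with Poisson
    log-linear rate regression, and a paired resampling study that contrasts
    MRR estimates with and without the misclassification in high- and
    low-incidence disease settings.
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
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
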