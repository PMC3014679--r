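Package: precool
Title: Intelligent Temperature Control for Fed-Batch Solvent Precipitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital twin of a jacketed fed-batch tank in which a proteolytic
    enzyme is precipitated with chilled ethanol, together with three intelligent
    temperature controllers that can be designed, trained and scored entirely in
    simulation: an incremental (velocity-form) Mamdani fuzzy-PI controller with
    centroid defuzzification, a Takagi-Sugeno neurofuzzy controller trained by
    hybrid least-squares/gradient learning to mimic the fuzzy-PI mapping, and a
    one-step-ahead model predictive controller built on a feedforward neural
    network trained with Levenberg-Marquardt. The plant model is calibrated
    exactly to published reaction-curve static gains, and closed-loop runs are
    scored with standard performance indices (overshoot, rise time, ITAE, pump
    saturation time, an energy proxy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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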