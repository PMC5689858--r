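Package: protonmu
Title: Output and Monitor-Unit Prediction for Double-Scattered Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts dose output (cGy/MU) for a compact passively
    double-scattered proton therapy system with 24 beam options, using three
    interchangeable models: a correction-based factor model driven by
    commissioning lookup tables (relative output, SOBP, range-shifter,
    off-center, field-size and gantry-angle factors), an analytical
    spread-out-Bragg-peak model in the dimensionless variable
    r = (R' - M')/M', and a quartic polynomial conversion of the analytical
    model. Includes commissioning-table management with strict 1-D/2-D linear
    interpolation, two-stage model fitting, a synthetic machine generator that
    emulates a full measurement campaign, validation statistics, and an
    uncertainty budget by quadrature error propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
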