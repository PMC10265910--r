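Package: gaitdmo
Title: Digital Mobility Outcomes from a Single Lower-Back Accelerometer
Version: 0.1.0
Authors@R: person("Mobility", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection of gait sequences, foot initial contacts, cadence and
    stride length from triaxial lower-back acceleration recordings, together
    with the technical-validation framework used to benchmark such
    algorithms: windowed gait/non-gait classification, tolerance-based
    initial-contact matching, Bland-Altman agreement, ICC(2,1), error-versus-
    speed/duration modelling, and a weighted benefit/cost performance index
    for ranking algorithms. Includes a physics-based synthetic gait signal
    generator with exact ground truth for end-to-end evaluation.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
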