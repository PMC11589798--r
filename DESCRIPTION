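Package: paequity
Title: Microsimulation of Health and Economic Outcomes of Sex Disparities
    in Youth Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based microsimulation of US children and adolescents
    (ages 6-17) coupling a daily energy-balance weight-dynamics model in
    childhood to an annual-cycle Markov model of weight-related disease in
    adulthood and a discounted cost/QALY engine.  A scenario engine
    interpolates female physical-activity and sports-participation
    parameters toward male levels to estimate overweight/obesity cases
    averted, disease cases and deaths averted, QALYs gained, and direct
    medical plus presenteeism cost savings under partial or complete
    elimination of the sex disparity, using common random numbers for
    paired baseline/counterfactual comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
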