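Package: seedhtt
Title: Thermal, Hydro and Hydrothermal Time Models for Seed Germination
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-based threshold models for seed germination under
    temperature and osmotic stress: thermal-time, hydrotime and
    hydrothermal-time (HTT) constants, repeated probit regression fits of
    the hydrotime and HTT models, cardinal-temperature estimation from
    germination-rate regressions, twelve classical germination and vigor
    indices, and a forward simulator of factorial Petri-dish germination
    experiments with seed-to-seed variation in base water potential.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
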