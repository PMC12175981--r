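Package: volatrank
Title: Olfactory Attractiveness Modeling from Volatile Profiles and Two-Choice Bioassays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving insect attractiveness rankings of food products
    from two-choice olfactometer trials, screening volatile (GC-MS) proportion
    profiles for odorants associated with those rankings, expanding significant
    odorants into a key-odorant biomarker panel by correlation pattern search,
    scoring unknown products against ranked benchmarks with a zero-intercept
    least-squares similarity index (the chem-index), and validating predicted
    attractiveness against paired trap-arena catches. Includes a synthetic-data
    generator that plants known attractiveness structure into compositional
    volatile profiles so every pipeline stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
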