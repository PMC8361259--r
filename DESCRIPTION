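Package: pulsekin
Title: Pulse-Chase Deuterium Labeling Kinetics of Blood and Airway Granulocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of in-vivo 6,6-2H2-glucose pulse-chase labeling
    experiments on eosinophils and basophils. Converts raw GC-MS isotopomer
    peak areas into calibrated, background-corrected and precursor-normalized
    DNA deuterium enrichment; simulates label kinetics under a first-in
    first-out (conveyor-belt) model of granulocyte production with blood and
    airway compartments; fits kinetic parameters; compares up- and
    downlabeling phases between treatment arms with two-line ANCOVA and exact
    nonparametric rank tests; and generates complete synthetic two-arm,
    two-phase labeling trials so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
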