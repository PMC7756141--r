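Package: paleoflight
Title: Aerodynamic Feasibility Analysis for Membrane-Winged Fossil Gliders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs wing planforms for membrane-winged theropods and
    other small paravians, and evaluates their flight potential: wing loading
    against flight and glider-envelope thresholds, the mechanical
    power-required curve (induced, parasite and profile power) against burst
    muscle power available, terrestrial take-off by running, leaping,
    flap-assisted running and wing-assisted incline running (WAIR), and
    equilibrium gliding performance (best glide speed, sink rate, glide ratio
    and banked-turn radius). Includes a synthetic-specimen generator for
    comparative glider and powered-flyer populations and tidy report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
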