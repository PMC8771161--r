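Package: olflineup
Title: Automated Olfactometer Line-Up Controller for Detection-Dog Research
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hardware-agnostic controller and simulator for a three-port
    olfactometer line-up used in detection-dog research: counterbalanced
    trial scheduling with blank (catch) trials, infrared beam-break event
    scoring of nose-poke alerts and all-clear responses, training-phase
    progression rules, session CSV logging, a parameterised virtual-dog
    agent for closed-loop simulated sessions (including odor-unplugged
    control sessions), and photoionization-detector trace analysis for
    odor delivery and clearance validation (low-pass filtering, per-cycle
    baseline drift correction, epoch metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
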