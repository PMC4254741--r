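Package: axobot
Title: Simulation and Image-Guided Targeting for Automated C. elegans Laser Axotomy
Version: 0.1.0
Authors@R:
    person("Axobot", "Developers", email = "axobot@example.org", role = c("aut", "cre"))
Description: A closed-loop simulator and analysis toolkit for fully automated
    femtosecond-laser axotomy of C. elegans touch neurons in a microfluidic
    trap. Provides a virtual microscope rig (worm phantoms, bright-field and
    fluorescence rendering with defocus blur and sensor noise, coarse stage
    and hysteretic piezo models, geometric laser ablation), the four-step
    targeting pipeline (worm centroid localization, soma detection by
    thresholded circular-feature search, ALM neuron verification via
    straight-edge evidence in flanking regions, and sub-pixel axon alignment
    by proportional control), a valve-program automation state machine with
    per-worm attrition bookkeeping, and the accompanying statistics
    (attrition summaries and Fisher's exact 2x2 test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
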