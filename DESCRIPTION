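Package: loomstrike
Title: Looming-Stimulus Models, Attack Kinematics and Escape Ethograms for
    Predator-Prey Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing escape behaviour of perching insects under
    aerial predator attack. Models the angular-size kinematics of virtual
    looming stimuli (size-to-speed ratio parameterisation), reconstructs
    smoothed three-dimensional attack kinematics (speed, acceleration,
    prey-centred elevation and azimuth, retinal angular size) from digitized
    high-speed video points, derives take-off timing and short/long escape-mode
    classifications from ethogram annotations, and computes prey-survival
    competition indices with their associated statistics. Includes seeded
    synthetic-data generators emulating hover-then-dart attack trajectories,
    bimodal take-off-duration ethograms and binomial consumption trials, so
    every pipeline stage can be exercised and validated without raw videography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
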