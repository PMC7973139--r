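Package: enactraff
Title: Quantitative Analysis of ENaC Surface Trafficking from Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying epithelial sodium channel (ENaC) regulation
    in Xenopus oocyte expression systems: amiloride-sensitive and
    hemichannel-mediated whole-cell current metrics from annotated
    two-electrode voltage-clamp traces, current-voltage analysis with
    reversal-potential estimation and cation permeability ratios, a
    sulfhydryl-modification (MTSET) protocol calculus that estimates the rate
    of channel retrieval from the plasma membrane with an insertion
    correction, the forward two-pool trafficking model that calculus inverts,
    and amplitude-histogram analysis of single-channel patch recordings
    (unitary current, NPo, apparent open probability, chord conductance).
    Includes seeded synthetic-data generators with known ground truth for
    every analysis stage and a scriptable pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
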