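Package: incmusic
Title: Incoherent MUSIC Imaging for Differential Microwave Brain Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and imaging toolchain for helmet-style multistatic
    microwave monitoring of evolving brain lesions such as hemorrhagic
    stroke. Provides frequency-dependent tissue dielectric tables, a layered
    head-phantom scenario builder, a linear (Born) forward model that
    synthesizes differential multistatic scattering matrices over a
    multifrequency sweep, the differential Incoherent MUSIC imaging
    algorithm with an Incoherent Migration baseline, binary target
    detection, and the signal-to-clutter ratio, signal-to-mean ratio and
    spatial-displacement reconstruction metrics. Includes readers and
    writers for multiport Touchstone snapshots and a command-line pipeline
    for simulate/image/score studies.
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
    withr,
    optparse
Config/testthat/edition: 3
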