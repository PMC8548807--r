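Package: rhabdomR
Title: Light Transport in the Butterfly Rhabdom and Opponent Photoreceptor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal slab model of light transport, rhodopsin-metarhodopsin
    photoconversion and effective spectral sensitivity in the fused rhabdom of
    nymphalid butterflies, including tapetal reflection and a red perirhabdomal
    screening pigment. Companion electrophysiology toolkit: sigmoid
    intensity-response fitting, reverse transformation of response amplitudes to
    spectral and polarization sensitivities, decomposition of green-depolarizing /
    red-hyperpolarizing (G+R-) opponent units, and a seeded generator of synthetic
    intracellular recordings for parameter-recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
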