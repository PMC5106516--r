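Package: epimusc
Title: Lumped-Stiffness Modelling of Epimuscular Myofascial Force Transmission
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating and applying lumped piecewise-linear stiffness
    models of intermuscular and extramuscular myofascial force transmission
    between synergistic muscles, developed for the rat soleus (SO) and lateral
    gastrocnemius plus plantaris (LG+PL) preparation. Implements extraction of
    isometric tendon forces from stimulation waveforms, the three-condition
    resection estimator of pathway forces, piecewise stiffness fitting with
    symmetry averaging, sensitivity analysis in the neurovascular length-ratio
    parameter, forward prediction of proximal-distal tendon force differences
    under proximal-only repositioning, Bland-Altman agreement statistics, and a
    seeded synthetic-experiment generator emulating the in situ protocol.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
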