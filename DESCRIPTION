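Package: eccperm
Title: Charge-Scaling Force-Field Tools and Permeation Analysis for
    Potassium-Channel Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for preparing and analysing molecular dynamics
    simulations of potassium channels with Electronic Continuum
    Correction (ECC) charge scaling. Applies charge scaling to
    GROMACS-style topologies in two force-field conventions, generates
    radius-corrected ion Lennard-Jones parameters by anchor
    interpolation with Born-model solvation targets, fits first
    solvation-shell radii from ion-water radial distribution functions,
    discretizes trajectories into 6-letter selectivity-filter occupancy
    codes, counts permeation events and converts them to single-channel
    conductance and current-voltage curves, and builds permeation
    mechanism graphs with mean-first-passage-time rates, progressive
    state lumping and rate-limiting-step identification. Synthetic
    state-level and coordinate-level trajectory generators with known
    ground truth make every analysis stage testable without MD output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
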