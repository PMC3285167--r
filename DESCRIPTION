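Package: smdpmf
Title: Steered-Dynamics Work Ensembles and Jarzynski Free-Energy Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for recovering potentials of mean force from replicate
    steered (nonequilibrium) dynamics. Defines linear-combination-of-distances
    (LCOD) collective variables with harmonic path restraints and flat-well
    spherical restraints, simulates Langevin dynamics on analytic model
    potentials with exact free-energy oracles, runs replicate steering
    protocols with snapshot-based initialization and per-replicate seeds,
    accumulates thermodynamic work, and estimates free-energy profiles by
    Jarzynski exponential averaging with a finite-sample bias correction and
    mean-square-error bands. Includes proton-transfer event detection on
    donor-hydrogen-acceptor difference coordinates, concomitance analysis,
    and pathway classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
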