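Package: miniqmmm
Title: A Miniature QM/MM Molecular Dynamics Engine with Link Atoms and
    Embedding Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained hybrid quantum-mechanics/molecular-mechanics
    (QM/MM) molecular dynamics engine for method development and teaching.
    Implements a classical force field (harmonic bonded terms, Lennard-Jones,
    generalized reaction-field electrostatics, SHAKE constraints), leapfrog
    dynamics with weak-coupling thermostat and barostat, three QM/MM embedding
    schemes (mechanical embedding with constant or dynamic charges, and
    electrostatic embedding), a hydrogen link-atom scheme with chain-rule
    force redistribution, distance-based scaling of MM point charges, periodic
    visibility checks for the QM zone, and a file-protocol contract for
    external quantum-chemistry programs exercised by an analytic mock backend.
    Ships trajectory observables used to validate such couplings: radial
    distribution functions, vibrational power spectra from autocorrelation
    functions, hydrogen-bond statistics and lifetimes, improper-dihedral
    series, and a vaporization-enthalpy estimator, together with synthetic
    fixtures (SPC water boxes, a toy tripeptide) so everything runs without
    external data or programs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
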