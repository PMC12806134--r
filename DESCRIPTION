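Package: asymem
Title: Construction Arithmetic and Biophysical Observables for Asymmetric Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing planar, asymmetric lipid bilayer
    systems. Covers the construction arithmetic used to build leaflet-area-matched
    asymmetric membranes (integer apportionment of lipid compositions, area-matching
    offsets, deliberate lipid-number mismatch, cholesterol asymmetry, and
    double-bilayer two-compartment systems with ion bookkeeping) and the standard
    structural and mechanical observables of membrane simulations: lateral area
    statistics, mass and charge density profiles, bilayer thickness, lipid tilt
    distributions, acyl-chain order parameters, Irving-Kirkwood lateral pressure
    profiles with surface tension, transmembrane electrostatic potentials by double
    integration of the charge density, and water permeation event detection with
    dwell-time statistics. A seeded synthetic-trajectory generator with analytic
    ground truth makes every observable verifiable without running molecular
    dynamics.
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
    yaml,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
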