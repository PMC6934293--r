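Package: coildeploy
Title: Finite-Element Simulation of Endovascular Coil Embolization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates endovascular coil embolization of intracranial
    aneurysms with explicit beam dynamics. Coil pre-shapes are generated by
    virtual mandrel winding, beam elements receive helical-spring equivalent
    elastic moduli, and the three mechanical steps of coiling (packaging
    into the catheter, advancement along the parent artery, deployment into
    the aneurysm sac) are simulated with corotational Timoshenko beam
    elements, central-difference time integration, Rayleigh damping and
    penalty contact against rigid triangulated surfaces. Deployed coil
    distributions are quantified on sequential cross-sections with coil
    density and gliding-box lacunarity, and compared in standardized
    coil-density/lacunarity space via Euclidean distances and univariate
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
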