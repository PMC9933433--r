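Package: aptIR
Title: Atomic Polar Tensors and Infrared Spectra from Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes atomic polar tensors (APTs, the derivatives of the total
    dipole moment with respect to atomic positions) by central finite
    differences of a pluggable dipole backend, fits an exactly E(3)-equivariant
    symmetry-adapted message-passing regressor that predicts per-atom 3x3 polar
    tensors from local atomic environments, and assembles infrared absorption
    spectra from molecular-dynamics trajectories via the dipole-velocity time
    autocorrelation function, including APT-weighted spectral decompositions
    into atomic-group contributions. Ships a synthetic periodic water-box
    generator with analytic toy dipole surfaces whose APTs have closed forms,
    so the whole labelling-training-spectrum loop can be validated without any
    electronic-structure code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'aptIR-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'trajectory-io.R'
    'fd.R'
    'graph.R'
    'irreps.R'
    'features.R'
    'model.R'
    'spectrum.R'
    'synthetic.R'
    'cli.R'
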