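Package: mlal
Title: Active Learning for Reactive Machine-Learning Potentials in Explicit Solvent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptor-driven active learning for training reactive
    machine-learning interatomic potentials in explicit solvent, together
    with a reaction-dynamics analysis stack. Provides SOAP-style global
    descriptors and the similarity kernel, three structure selectors
    (energy threshold, kernel similarity, local-outlier-factor distance),
    an MD-episode active-learning loop with cubic episode scheduling,
    solvent-cluster carving, a kernel-ridge-regression potential over
    global descriptors, velocity-Verlet/Langevin molecular dynamics with
    harmonic biases, umbrella sampling with WHAM free-energy
    reconstruction, downhill/uphill reactive trajectory ensembles with
    bond-formation time-gap statistics, radial distribution functions and
    hydrogen-bond analysis. Built-in analytic toy potentials (flexible
    point-charge water, a two-bond double-well reactive model) stand in
    for ab initio reference calculations so the whole workflow runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
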