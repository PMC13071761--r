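Package: ptmdyn
Title: Comparative Trajectory Analysis of Redox-Modified Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for comparing molecular-dynamics ensembles
    of an enzyme-regulator complex in a fully reduced versus a cysteine-modified
    (PTMed) state. Implements rigid-body superposition, per-residue fluctuation
    statistics, common-eigenspace principal component analysis with
    mode-contribution mapping, dynamic cross-correlation matrices and a
    correlation-redistribution score, active-site gate-state classification and
    band occupancies, geometric hydrogen-bond detection, residue-residue
    nonbonded interaction energies with layered flow-graph construction, and
    Bennett-acceptance-ratio free-energy estimation with relative binding
    free-energy and L1 summaries. A synthetic-ensemble generator with known
    ground truth (Gaussian fluctuation models, Markov gate dynamics,
    Crooks-consistent work samples) makes every analysis stage testable without
    running molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
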