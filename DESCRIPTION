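Package: cgassoc
Title: Coarse-Grained Kinetic Monte Carlo Simulation of Protein-Protein
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid-body kinetic Monte Carlo simulation of protein-protein
    association using a two-site-per-residue coarse-grained model. Proteins
    are reduced to Calpha plus side-chain functional-center sites, diffuse
    in a periodic box under a hybrid force field that mixes a physics-based
    potential (Kim-Hummer screened electrostatics, Kyte-Doolittle
    hydrophobicity, excluded volume) with a Go-like statistical contact
    potential derived from interface pair statistics under the
    quasi-chemical approximation. Ensembles of trajectories yield
    association probabilities that are converted to association rate
    constants, with trajectory-level analysis of binding energy, RMSD to
    the native complex, encounter-complex criteria and ligand spatial
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
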