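Package: rxn3d
Title: Symmetry-Adapted Graph Networks for Reaction Barrier Prediction
    from 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts scalar reaction properties (activation barriers,
    kcal/mol) from the three-dimensional structures of reactants and
    products.  Molecules are encoded by invariant or E(3)-equivariant
    tensor-product convolutions over radius graphs with spherical-harmonic
    filters; reactant and product representations are combined under three
    atom-mapping regimes (true maps, externally produced maps, or none,
    via cross-attention or global pooling) and read out in vector or
    atomic-energy mode.  Includes xyz and atom-mapped reaction SMILES
    parsing, SMILES-to-xyz matching by labelled graph isomorphism,
    reaction-type signatures, dataset curation, random/scaffold/size/
    property splits, a plateau-scheduled training loop with early stopping,
    and synthetic fixtures (homometric and angle probes, additive-energy
    reaction sets) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
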