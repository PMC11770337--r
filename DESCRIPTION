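Package: pottspep
Title: Potts-Model Design of Plastic-Binding Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence design of short plastic-binding peptides on a fixed
    adsorbed conformation. Builds one-body and two-body energy tables from a
    simplified molecular-mechanics plus generalized-Born energy with
    side-chain coarse-graining and lowest-energy rotamer reduction, scores
    sequences with a Potts model, solves the design problem through a one-hot
    QUBO encoding with exhaustive enumeration, simulated annealing and a
    decomposition refiner, explores degenerate near-optimal sequences with a
    proximal-policy-optimization agent, and profiles candidate peptides
    (net charge, isoelectric point, mass, amino-acid frequencies, side-chain
    geometric environment preferences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
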