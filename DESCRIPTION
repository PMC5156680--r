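Package: psnscan
Title: Protein Structure Networks, Saturation Mutagenesis Aggregation and
    NMR Validation for Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of proteins as
    residue interaction networks. Builds persistence-filtered protein
    structure networks (PSNs) from multi-model PDB ensembles using
    side-chain centre-of-mass contacts, and analyses hubs, connected
    components, shortest communication paths, cutoff sensitivity and
    jack-knife convergence. Aggregates per-conformer saturation-mutagenesis
    free-energy predictions with an empirical linear correction and
    classifies stability versus binding hotspots. Cross-validates ensembles
    against NMR observables (chi-square on chemical shifts, NOE distance
    differences, RMSIP subspace overlap). Includes lightweight annotation
    utilities (variant-predictor consensus, docking-energy filtering,
    paired tumour/normal expression network values) and synthetic-data
    generators with planted ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
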