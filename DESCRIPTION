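Package: mcdpa
Title: Multi-Chain Dynamics Perturbation Analysis for Ligand-Binding
    Region Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts small-molecule binding regions on proteins and
    protein-protein complexes from coarse-grained elastic network models.
    Surface test points (probes) perturb the harmonic conformational
    ensemble; each probe is scored by the Kullback-Leibler divergence
    between the perturbed and unperturbed Gaussian distributions of
    internal motions, and high-scoring probes are clustered into ranked
    binding-region predictions. Inter-chain springs with an adjustable
    force constant couple the chains of a complex, so the effect of a
    protein-protein interaction on predicted ligand-binding regions can
    be quantified: predictions from the monomer and the complex are
    compared through overlap-based precision/recall and a six-way change
    taxonomy, and bound-ligand displacement is measured by ARMSD after
    superposing the shared protein.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
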