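Package: macrorew
Title: Reweighted Conformational Ensemble Analysis for Macrocycles from
    Accelerated Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for dual-boost accelerated molecular
    dynamics (aMD) ensembles of macrocyclic molecules. Converts per-frame
    boost energies into statistical weights by exponential or
    Maclaurin-truncated reweighting, builds reweighted histograms and
    free-energy surfaces, performs dihedral principal component analysis
    (sin/cos encoding) with K-means clustering and representative-frame
    selection, detects intramolecular hydrogen bonds under geometric
    criteria and accumulates reweighted contact maps, quantifies
    trajectory convergence (pairwise heavy-atom RMSD matrices, split-half
    contact and density divergences, cross-run overlap), and averages
    conformer partial-charge tables. A synthetic-data generator produces
    toy macrocycle topologies, Metropolis samples from boosted potentials
    with exact boost energies, planted torus clusters, and trajectories
    with planted hydrogen-bond occupancies, so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
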