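Package: profclust
Title: Profile Hashing and Linear-Time Consensus Ranking for
    Macromolecular Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranking and clustering of large ensembles of protein and RNA
    3D models via 1D structural profiles.  Projects coordinates into
    discrete state profiles (secondary structure/solvent accessibility,
    pseudo-secondary structure/contact number, binary contact maps,
    Leontis-Westhof and torsion-angle RNA states) or fixed-dimension
    bag-of-fragments frequency profiles; ranks all models by an implicit
    all-pairs consensus (1D-jury) in linear time; hashes profiles into
    binary keys against the consensus reference to form micro-clusters;
    and provides three hashing-based clustering heuristics (entropy-driven
    key coarsening, reference-based partitioning, and approximate
    average-linkage hierarchical clustering over micro-cluster centroids)
    together with Kabsch RMSD and MaxSub structure similarity kernels and
    model-quality-assessment evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
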