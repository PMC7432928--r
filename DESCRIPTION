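Package: priddg
Title: Predicting Protein-RNA Binding Affinity Changes upon Missense
    Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in protein-RNA binding free energy
    (ddG, kcal/mol) caused by single missense mutations in RNA-binding
    proteins.  A multiple linear regression scoring function combines
    eight structure-based features (van der Waals and electrostatic
    interaction energy differences, interface size, surface-area ratios,
    residue-network closeness centrality, solvent-accessibility and
    secondary-structure descriptors) with three sequence-based features
    (hydrophobicity-scale and amino-acid composition differences).
    Includes PDB reading/writing, mutant side-chain modelling with
    restrained energy minimization, Shrake-Rupley solvent-accessible
    surface areas, a hydrogen-bond based secondary-structure assignment,
    dataset curation, cross-validation protocols (repeated random splits
    and leave-one-complex-out) and ROC/precision-recall/MCC evaluation,
    plus deterministic generators of toy protein-RNA complexes and
    synthetic training tables for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
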