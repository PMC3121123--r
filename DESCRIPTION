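Package: DNABindStack
Title: Stacked Meta-Prediction of Protein DNA-Binding Residues
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for residue-level prediction of protein DNA-binding
    sites by stacking the outputs of several sequence-based base predictors
    with a radial-basis-function support vector machine. Provides
    structure-derived gold-standard annotation of binding residues from
    protein-DNA complexes (any-atom distance criterion and solvent-accessible
    surface-area change criterion, with a built-in Shrake-Rupley SASA
    engine), class-imbalance undersampling, residue- or protein-level
    cross-validation, the six standard performance measures with
    confusion-count reconstruction from published rates, a spatial-clustering
    false-positive filter on C-alpha coordinates, and a synthetic-data
    generator that emulates protein-DNA complexes and correlated
    base-predictor score tracks so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    bio3d,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
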