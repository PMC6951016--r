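Package: molmpnn
Title: Message Passing Neural Networks for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Graph neural networks for bioactivity and physical-chemical
    property prediction from SMILES: a SELU-activated message passing
    baseline, an attention-aggregation variant (AMPNN), and a
    directed-edge memory network (EMNN), together with charge-parent
    standardization and missing-label masking (SMD preprocessing),
    random and Bemis-Murcko scaffold splitting, masked multitask losses
    and metrics, a three-repeat evaluation protocol, and Gaussian-process
    Bayesian hyperparameter search with batch suggestion. Molecule
    perception is delegated to the RDKit toolkit through a bundled
    Python helper; the neural network layers and their reverse-mode
    differentiation are implemented in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python'
Config/testthat/edition: 3
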