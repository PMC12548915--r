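Package: cypdfi
Title: CYP450-Guided Attention Regularization for Drug-Food Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pairwise drug-food interactions (DFI) from SMILES with a
    cross-attention model whose attention between CYP450 isoenzyme embeddings
    and compound substructure embeddings is regularized, semi-supervised, by
    drug-CYP450 interaction (DCI) labels through trainable pseudo-substructure
    embeddings. Provides ECFP substructure featurization with bit-to-atom
    provenance, an edge-attributed graph encoder, Butina-cluster cold-drug and
    cold-food evaluation splits, a synthetic benchmark generator with planted
    DCI/DFI structure, and attention-based interpretation of trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pheatmap
SystemRequirements: Python (>= 3.8) with rdkit, available as 'python' on PATH
Config/testthat/edition: 3
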