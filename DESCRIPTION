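Package: ptmtune
Title: Multi-Task Prediction of Post-Translational Modification Sites by
    Prompt Tuning a Frozen Residue Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building per-residue post-translational modification
    (PTM) site prediction models on top of a frozen protein residue-embedding
    encoder. The package constructs labeled corpora from full-length protein
    sequences and UniProt-style site annotations, initializes trainable task
    prompts by K-means clustering of mean-pooled 21-residue PTM-site window
    embeddings, and trains a shared inception-CNN decoder with task-specific
    classification heads. Multi-task models are trained by knowledge
    distillation: single-task teachers supply soft labels that are blended
    with ground truth via a fixed or annealed mixing weight and combined in a
    dataset-size-weighted loss. A deterministic toy self-attention encoder,
    a seeded motif-driven corpus simulator, and the standard evaluation
    metrics for imbalanced site prediction (F1, MCC, AUROC, AUPRC) make the
    whole pipeline testable at desk scale without external model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
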