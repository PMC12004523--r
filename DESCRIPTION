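Package: lbvscreen
Title: Ligand-Based Virtual Screening with Similarity-Constrained
    Validation and Early-Enrichment Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for ligand-based virtual screening of
    cytochrome P450 aromatase (CYP19A1) inhibitors and similar targets:
    structure standardization and bioactivity labeling for potency-based
    (pChEMBL-style) and score-based (PubChem-style) sources, chemical-space
    analysis (ECFP4 fingerprints, physicochemical descriptor panels, PCA,
    Murcko scaffold census, nearest-neighbor similarity profiles),
    similarity-constrained cross-validation via Butina sphere-exclusion
    clustering, SMOTE oversampling inside training folds, random-forest
    model selection by BEDROC early enrichment, and a multi-stage compound
    triage funnel (rule of five, CYP motif, ensemble probability/rank gate,
    novelty, PAINS and structural liabilities, diversity clustering) with a
    full per-stage audit trail. Includes a synthetic-library generator with
    a planted structure-activity rule so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
SystemRequirements: OpenBabel (obabel on PATH for batch fingerprinting)
Config/testthat/edition: 3
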