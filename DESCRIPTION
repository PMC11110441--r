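Package: biochemlm
Title: Potency-Conditioned Generative Design of Active Compounds from
    Protein Sequence Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A dual-component "biochemical language model" for generative
    design of active compounds with desired potency from target protein
    sequences. A pluggable protein-sequence embedder produces a fixed-size
    target embedding that is concatenated with a discretized compound-potency
    token embedding and fed to a conditional encoder-decoder transformer,
    which decodes SMILES strings of candidate compounds. The package covers
    activity-data curation (pKi aggregation by geometric mean, confidence
    filtering), residue/SMILES/potency-bin tokenization, analogue-series
    identification by matched-molecular-pair fragmentation with
    retrosynthetic cut rules, structurally disjoint fine-tuning/test
    splitting, pre-training and per-class fine-tuning with gradient
    accumulation, multinomial candidate sampling, and evaluation statistics
    (exact reproduction counts, 1-nearest-neighbor Tanimoto similarity,
    potency-distribution comparison, synthetic-accessibility scores), plus a
    synthetic toy-world generator so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as "python" on
    the PATH (used for SMILES canonicalization, fragmentation, fingerprints
    and synthetic-accessibility scoring)
Config/testthat/edition: 3
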