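Package: backsplicer
Title: Attention-Based Circular RNA Prediction and Zero-Shot Backsplice Discovery
Version: 0.1.0
Authors@R: person("backsplicer", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts circular RNAs (circRNAs) from the sequence context of
    splice junctions alone. Each acceptor and donor junction is represented by
    the k-mer embeddings of a short flanking window, encoded with bidirectional
    GRUs and attention pooling; a cross-attention layer models interactions
    between acceptor and donor sites, and a second attention layer aggregates
    sites into a gene-level representation scored by a sigmoid head. After
    training only on binary circRNA labels, the donor-side attention weights
    factor into a joint probability over (donor, acceptor) pairs, ranking
    candidate backsplice junctions with zero pair-level annotation. Includes a
    seeded synthetic-gene simulator with planted junction motifs, grouped
    cross-validation utilities, standard binary classification metrics, and a
    command-line interface covering the simulate/train/predict/discover/evaluate
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
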