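Package: g4boost
Title: Sequence-Based Prediction of DNA G-Quadruplex Stability with
    Gradient Boosted Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects extended putative G-quadruplex sequences (PQSs) on
    both strands of DNA, digests each PQS together with its 50-nt flanks
    into 209 sequence-derived features (overlapping triad and singleton
    contents, motif topology, and hairpin ensemble folding free energies
    of the loops), maps per-bin G4-seq base-mismatch levels (mm%) onto
    PQS sites, and trains a gradient boosted tree regressor of mm% with a
    repeated cross-validation tuning workflow.  Fitted models classify
    PQSs into stable versus non-forming G4s at an mm% operating
    threshold.  A synthetic-genome simulator with planted PQSs and a
    matching bimodal mm% track supports end-to-end validation without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    xgboost,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
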