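Package: forktrace
Title: Replication Fork Calling, Stall Scoring and Stress Signatures from
    Nanopore Base-Analogue Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for single-molecule DNA replication experiments in
    which nascent DNA is labelled by a sequential EdU/BrdU pulse-chase and
    read out as per-thymidine analogue probabilities on long nanopore reads.
    Segments each read into analogue-positive tracks, pairs them into
    replication forks, origins and terminations, measures fork speed with
    principled exclusion rules, computes a softplus-scaled fork stall score,
    builds eight-feature per-fork replication-stress signatures with UMAP
    embedding and K-means clustering, maps forks to replication timing (Trep)
    from multi-fraction Repli-Seq profiles and tests S-phase trends, and
    estimates treatment effects with a hierarchical Bayesian model sampled by
    a built-in No-U-Turn sampler with ROPE-based significance. A pulse-chase
    simulator with full ground truth makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    jsonlite,
    uwot,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
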