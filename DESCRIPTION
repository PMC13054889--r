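Package: synthreward
Title: Synthesis-Aware Reward Functions for Generative Molecular Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reward functions that score generated molecules by the quality,
    similarity and batch-level coherence of their retrosynthetic routes.
    Parses route trees (a native JSON schema and an AiZynthFinder-style
    dialect) annotated with hierarchical reaction-taxonomy codes, and
    implements two extrinsic rewards (a synthetic-feasibility score built
    from stock availability, reaction preference and step-count factors,
    and a reference-route similarity score based on tree edit distance
    with hierarchically scaled rename costs) and two intrinsic rewards
    (batch-level route popularity and a cross-batch plate-filling reward
    with persistent ledger state). A weighted geometric-mean combiner and
    a seeded desk-scale simulator exercise the rewards inside a toy
    generation loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
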