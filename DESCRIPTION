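Package: hconnica
Title: Hybrid Functional-Structural Connectome Trait Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of robust, task-sensitive joint functional-structural
    connectivity traits from a cohort of brain connectomes. Raw structural
    connectomes (streamline weights) are log-transformed and converted to a
    structural-correlation representation restricted to the population
    common-edge mask; functional and structural edge profiles are concatenated
    into a hybrid subject-by-edge matrix, denoised by PCA at a fixed explained
    variance, and decomposed by multi-run FastICA. Components recurring across
    bootstrap runs are clustered into robust hybrid traits with per-subject
    weights, scored for task sensitivity by one-way intraclass correlation,
    and mapped back to brain networks through joint extreme-value edge masks
    and nodal strength. Includes a degree-preserving edge-swap null model for
    structural connectomes and a synthetic cohort generator with planted
    traits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
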