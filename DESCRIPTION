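Package: perturbEHT
Title: CRISPR Activation Perturb-Seq Analysis of the Endothelial-to-Haematopoietic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for inducible CRISPR-activation (CRISPRa)
    perturbation single-cell RNA-seq experiments during endothelial-to-
    haematopoietic differentiation. Provides candidate transcription-factor
    discovery by cross-dataset marker and detection-fraction gating,
    guide-capture cell assignment with library-specific filters, target
    activation and cluster-composition inference, guide enrichment and
    differential-expression analysis for downstream-effector discovery,
    gene-set over-representation, and Seahorse XF ATP-rate partitioning.
    A ground-truthed synthetic-data generator emulating the experimental
    design (reference panels, four perturbation libraries, guide capture,
    Seahorse traces) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
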