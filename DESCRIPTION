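Package: tmetools
Title: Tumor Microenvironment Analysis from Single-Cell and Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("TME", "Tools Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for dissecting the tumor
    microenvironment of hepatocellular carcinoma (and similar multi-site
    tumor atlases) from single-cell RNA-seq together with bulk cohorts.
    Implements per-cell quality control and log2 library-size
    normalization; three-criterion Wilcoxon marker calling; tissue
    preference via the observed/expected ratio (Ro/e) with chi-squared
    tests; cluster similarity by weighted shared-marker fold-change
    scoring and by a ridge-penalized multinomial classifier; k-means
    subclustering of cytotoxic T cells into exhaustion states;
    permutation-based ligand-receptor interaction scoring with
    communication networks and ligand-pathway correlation networks;
    marker-gene-sum deconvolution of bulk RNA-seq with tertiary lymphoid
    structure scoring and k-means microenvironment subtyping; and
    clustering robustness assessment by normalized mutual information
    under down-sampling and leave-one-patient-out protocols. Ships a
    seeded synthetic-data generator with planted ground truth so every
    stage is testable without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
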