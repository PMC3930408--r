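Package: dystroscore
Title: Gene-List Overlap Meta-Analysis and Rank-Based Tumour-Signature
    Scoring for Muscular Dystrophy Transcriptomes
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare differential-expression gene lists from
    muscular-dystrophy studies against cancer-related gene lists with a
    finite-universe hypergeometric tail test, and to score ternary
    expression-direction profiles against a rank-based multi-category
    tumour classifier signature (per-gene contribution B = 1 - C*R with
    C = 1/HR). Includes the upstream stages that feed both computations:
    probe-to-GeneID list standardization with direction annotations,
    detection-call score aggregation, and delta-delta-Ct relative
    quantification of qPCR Ct matrices with one-way ANOVA significance
    calls. A seeded synthetic-data module generates every input format
    (gene-list pairs with controlled overlap, scoring tables, direction
    profiles with a controlled match fraction, Ct matrices with planted
    group shifts) so the whole pipeline is testable without external
    downloads, and a command-line pipeline ties the stages together with
    run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
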