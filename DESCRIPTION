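Package: t2dtwin
Title: Digital-Twin Components for Type 2 Diabetes Trajectory Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, prediction and knowledge-graph
    interpretation components for a type 2 diabetes digital-twin pipeline.
    Generates longitudinal multiomic cohorts with planted feature effects,
    applies a missingness/outlier filtering cascade with iterative
    random-forest imputation, trains cross-validated L1-regularized models
    that predict 6-month and 1-year changes in five clinical variables
    (HbA1c, glucose, insulin, HOMA-IR, eGFR), and interprets top-weighted
    predictors on a typed biomedical knowledge graph via Takahashi Steiner
    subgraphs, shortest paths to a disease node, and topic PageRank
    prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
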