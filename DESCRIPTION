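Package: fragnet
Title: Model-Agnostic Interpretation of Binary QSAR Classifiers via Feature Networks
Version: 0.1.0
Authors@R: person("fragnet", "maintainers", email = "fragnet@example.org", role = c("aut", "cre"))
Description: Interprets predictions of arbitrary binary (Q)SAR classifiers by
    enumerating sub-features of a query molecule (fingerprint bit combinations or
    reduced-graph structural fragments), organising them into a feature-network DAG,
    running the black-box model on every node, classifying each node into one of six
    assessment types (ACTIVATING, DEACTIVATED, DEACTIVATING, NEGATED,
    ACTIVITY_IDENTIFIED, IGNORE) and summarising the causes of a prediction as
    activating and deactivating atom-and-bond highlights. Includes a fragment-based
    applicability domain, ACTIVATING-feature mining across datasets, a minimal
    chemistry kernel (SMILES/MOL parsing, aromaticity and ring perception, canonical
    SMILES, substructure matching) and deterministic toy-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
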