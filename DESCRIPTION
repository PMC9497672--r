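Package: mitn
Title: Feature Selection via Mutual Information Transfer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric filter feature selection for classification by
    converting the choice of P features into a maximum-flow mixed-integer
    linear program over a mutual-information transfer network (MITN-ILP).
    Pairwise mutual information between discretized predictors forms arc
    capacities, the mutual information of each predictor with the class forms
    node supplies, and the selected subset is the one that lets a single
    terminal feature collect the most information flow. Includes plug-in
    estimators for entropy, mutual information, conditional and interaction
    information; the family of greedy forward baselines (MIFS-U, IGFS, CIFE,
    MRMD, MRI, mRMR, SPEC-CMI) as pluggable criteria in one generic engine;
    an exhaustive max-flow oracle for verification; a classifier benchmark
    harness; and a synthetic-data generator with planted informative,
    redundant and noise features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    e1071,
    MASS,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
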