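Package: rsadyn
Title: Model-Based Representational Similarity Analysis of Temporal and
    Layer-Wise Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based representational similarity analysis
    (RSA) of time-resolved neural data and layer-wise network activations:
    construction of representational dissimilarity matrices (RDMs) from
    feature matrices, idealized binary hypothesis RDMs for category
    structure, partial Spearman correlation and time- and layer-wise model
    RSA, commonality (variance-partitioning) indices, sign-flip
    cluster-based permutation inference, inter-subject noise ceilings,
    stimulus bootstrap and permutation tests, and occlusion-based class
    attribution with region-mask scoring. Includes synthetic-data
    generators that emulate two-stage category dynamics (e.g., face
    pareidolia represented first like faces, later like objects) so the
    full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
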