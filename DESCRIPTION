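Package: affectspace
Title: Individual Affective Spaces from Multi-Arrangement Similarity
    Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying individual differences in "affective
    spaces": geometric representations of emotional stimuli recovered
    from the multi-arrangement similarity task. Implements adaptive
    lift-the-weakest trial selection, inverse multidimensional scaling
    of partial 2D arrangements into full dissimilarity matrices,
    group-median agglomerative clustering with silhouette validation,
    a per-participant cluster-dispersion statistic, and all-subsets
    regression of dispersion on Big Five personality T-scores with
    BIC model selection and two Monte Carlo null procedures. Includes
    a synthetic-data generator that plants trait-dependent cluster
    dispersion so the whole pipeline can be exercised and validated
    by parameter recovery without any behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    ape
Suggests:
    cluster,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
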