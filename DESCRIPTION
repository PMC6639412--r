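Package: connherit
Title: Twin-Based Heritability and Plasticity Gradients of Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cortical plasticity as the complement of resting-state
    functional-connectivity heritability across a visual-area hierarchy.
    Provides a synthetic twin-cohort generator with known ground truth,
    nuisance-regressed Fisher-z connectivity tables, family-aware
    block-permutation screening with FDR control, covariate-adjusted AE
    variance-components heritability with mixture chi-square likelihood-ratio
    tests, test-retest ICC(3,1) and Mantel matrix association, graph-distance
    hierarchical levels, and gradient models including a two-component
    (short-/long-term plasticity) exponential decomposition compared by
    Akaike weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
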