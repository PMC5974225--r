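Package: SpineClusters
Title: Exact Combinatorial Analysis of Synaptic Input Clusters on Dendrites
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identification and characterization of clusters of synaptic
    inputs on dendritic segments and branched dendritic trees. Implements
    exact closed-form likelihoods for spatial input ensembles under the
    random-assignment null (order-based and distance-based treatments, on
    single segments and across branch points of a dendritic tree), the full
    six-step detection / classification / testing workflow (ensemble
    detection, specific ensemble likelihood, cluster classification, overall
    cluster likelihood, dataset-level binomial tests, cluster
    characterization), a seedable Monte-Carlo reshuffling baseline with its
    analytic error model, plain-text spine-table input/output, and synthetic
    data generators with planted ground truth. All arrangement counts are
    carried as exact arbitrary-precision integers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, Neuroscience, SpatialStatistics
RoxygenNote: 7.3.3
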