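Package: spikeprop
Title: Spatiotemporal Mapping of Interictal Spike Propagation in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects, constrains, cleans, and quantifies the spatiotemporal
    propagation of interictal spike discharges across 2D intracranial
    electrode arrays. Chains spike-detector events into multichannel
    sequences under leader-window and inter-spike-gap rules, reorders
    acquisition ties spatially, enforces partition and frequent-connection
    constraints, removes artifact-driven outlier trajectories by
    similarity-matrix degree clustering, and summarises the resulting spike
    frequency and recruitment-latency maps with Lorenz/Gini concentration
    statistics and the Moran Index of spatial autocorrelation, including
    permutation nulls and nonparametric outcome-group comparisons. A seeded
    simulator generates detector-style event streams with planted
    propagating wavefronts, background spikes, and artifact bursts for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
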