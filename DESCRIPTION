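Package: pnorg
Title: Spatial Organization and Synaptic Connectivity of Olfactory Projection Neurons
Version: 0.1.0
Authors@R:
    person("pnorg", "developers", email = "pnorg@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial organization of uniglomerular projection
    neurons (uPNs) across the three olfactory neuropils of the Drosophila brain
    (antennal lobe, mushroom body calyx, lateral horn) and the structure of their
    synaptic interfaces with third-order neurons. Provides SWC skeleton I/O,
    rotating-projection density segmentation of neuropils, the nearest-point
    inter-neuron distance, per-homotype bundling/packing/overlap statistics,
    complete-linkage clustering with a dynamic hybrid tree cut, categorical
    association tests (Pearson chi-square, bias-corrected Cramer's V, permutation
    mutual information), binarized bipartite connectivity statistics, tanglegram
    congruence indices, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
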