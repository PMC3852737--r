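Package: phenonet
Title: Temporal Structure of Bipartite Plant-Pollinator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for analysing the within-season temporal structure of
    bipartite plant-flower-visitor networks from daily observation records.
    Infers species phenophases, builds static, windowed and one-day network
    slices under the phenophase-overlap activity rule, and quantifies
    connectance, linkage level and the core/tail partition. Implements the
    NODF nestedness metric with equiprobable and degree-proportional null
    models, a mid-domain Monte Carlo test of tail-visitor phenophase
    segregation on core plants, and a directed time-delay framework that
    classifies every species pair as overlapping, gapped or temporally
    impossible and locates temporal-coupler chains. Ships a synthetic
    community generator emulating an arctic season so every pipeline stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: igraph, jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
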