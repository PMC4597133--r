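Package: gapkit
Title: Ecogeographic Gap Analysis and Niche Overlap for Crop Wild Relatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ex situ conservation gap analysis of crop wild
    relatives: occurrence-record cleaning and germplasm/reference
    partitioning, geodesic circular-buffer distributions, validation of
    externally produced habitat-suitability surfaces (five-fold AUC,
    across-fold stability, ROC thresholding, buffer fallback), sampling /
    geographic / ecological representativeness scores and collecting
    priorities, pairwise range and niche overlap (Schoener's D,
    Hellinger's I), environmental ordination and clustering, phylogenetic
    signal (Blomberg's K) and Mantel tests, plus a seeded synthetic-world
    generator so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    geosphere
Config/testthat/edition: 3
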