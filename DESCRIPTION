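Package: dcssdec
Title: Dual-Constraint Semi-Supervised Deep Embedded Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised deep embedded clustering with soft pairwise
    constraints. A stacked autoencoder learns a low-dimensional embedding of
    high-dimensional instances (e.g. flattened images); fuzzy cluster
    memberships are computed with a Student's-t kernel and refined by
    minimising a Kullback-Leibler self-training loss augmented with a
    "should-link" reward term and a "shouldNot-link" penalty term derived
    from ground-truth side information. Includes a seeded synthetic-data
    generator (Gaussian blobs and toy glyph images), constraint generation
    and file I/O, greedy layer-wise autoencoder pretraining, joint
    mini-batch optimisation of network weights and cluster centroids,
    Hungarian-matching clustering accuracy and normalized mutual
    information, named hyper-parameter presets, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
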