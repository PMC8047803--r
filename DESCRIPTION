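Package: pathsom
Title: Self-Organizing Map Analysis of Mechanical Unfolding Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs, visualizes and classifies conformational-transition
    pathways sampled by multiple steered molecular dynamics replicas.
    Conformations are featurized as native Cbeta contact distances, embedded on
    a non-periodic hexagonal self-organizing map (SOM), and each replica is
    traced as its per-frame best-matching-unit sequence. Pathway traces are
    compared with a codebook-space path distance and clustered; neuron-to-neuron
    transitions yield a row-stochastic matrix and a negative-log-probability
    graph for shortest-path analysis; per-frame scalars such as the pulling
    force are averaged per neuron to locate mechanical intermediates, and
    pulling work profiles are integrated from force-extension data. A synthetic
    unfolding generator with scripted contact-rupture orders provides
    ground-truth-labelled data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    igraph,
    cluster,
    pracma,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
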