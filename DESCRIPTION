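Package: traceimpute
Title: Imputation of Multiplexed DNA FISH Chromatin Traces Using
    Structural Neighbors and Single-Cell Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Completes undetected loci in chromatin-tracing (multiplexed DNA
    FISH) experiments. Spatial distance matrices are transformed into Gaussian
    proximity scores, structurally similar chromosome copies are found by
    Procrustes-aligned RMSD within RNA-defined cell neighborhoods, and missing
    locus pairs are imputed by a per-genomic-distance constrained least-squares
    blend of neighbor DNA FISH and (optionally) neighbor single-cell Hi-C
    signal. 3D coordinates of undetected loci are then recovered by maximizing
    a Poisson log-likelihood anchored on the detected loci. Ships downstream
    analytics (insulation score, A/B compartments, clustering features,
    chromatin loop calling) and a synthetic multimodal data generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    igraph,
    mclust,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
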