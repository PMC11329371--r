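Package: fretfluor
Title: Spectroscopic Barcoding of Single Molecules in a Feedback Trap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-parameter identification of
    FRET-encoded DNA labels ("FRETfluors") measured one molecule at a time
    in an anti-Brownian electrokinetic (ABEL) trap. Provides a synthetic
    photon-stream simulator (Poisson arrivals, FRET branching, exponential
    nanotimes convolved with an instrument response function, acceptor
    photobleaching, size-dependent positional confinement), photon-by-photon
    change-point segmentation with AIC-optimised K-means background
    estimation, per-level brightness / FRET proximity ratio / maximum
    likelihood donor lifetime estimation, axis-aligned 3D Gaussian cluster
    models with pairwise misclassification matrices and compatible label-set
    selection, and diffusion-based wash-free bound/unbound discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    data.table,
    yaml,
    jsonlite,
    igraph,
    mclust,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
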