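Package: lofcEncode
Title: Clustering and Encoding-Model Analysis of Lateral Orbitofrontal Spike Trains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-unit spike trains recorded (or
    simulated) during a cued-gamble task in which auditory clicks convey
    reward volume and light flashes convey reward probability. The package
    generates synthetic sessions and Poisson ground-truth neurons, fits an
    L2-penalised Poisson encoding GLM with a log-raised-cosine temporal
    basis, clusters neurons by trial-averaged or condition-averaged response
    profiles, validates cluster number with the gap statistic, silhouette,
    subsampled adjusted Rand index and the PAIRS neighbour-angle statistic,
    and quantifies task-variable encoding with the coefficient of partial
    determination, sampling-based mutual information, shuffle-corrected
    discriminability, and trial-history regressions of epoch-averaged
    firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    cluster,
    mclust,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
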