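Package: pixlink
Title: Supervised Prediction of Gene Regulatory Links from Spatial
    Expression Image Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed transcription-factor to target-gene regulatory
    links from pairs of spatial gene-expression images (in situ hybridization
    style embryo images). Variable-size per-gene image sets are reduced to
    orientation-matched image pairs, classified by a convolutional network on
    the vertically concatenated pair, and per-pair probabilities are averaged
    into a link score. Includes a synthetic embryo-image generator with a
    planted ground-truth network, gene-level train/test splitting with
    leakage control, evaluation metrics (accuracy, F1, top-fraction false
    positive ratio, score histograms, hit ratio), top-K network extraction
    with hub-gene analysis and export, and occlusion sensitivity maps for
    model interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
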