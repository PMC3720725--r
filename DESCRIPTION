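Package: lacoquant
Title: Quantitative Analysis of Targeted Chromatin Array Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative side of lac-operator (lacO) array
    targeting experiments: simulation of ground-truthed 3D confocal stacks
    of nuclei carrying compact or fibrillar chromatin domains, segmentation
    and 3D morphometry of the array (volume, mesh surface area, and the
    surface factor, a sphericity-type shape statistic), classification of
    decondensed arrays against a control quantile, normalization and
    bi-exponential decomposition of FRAP/FLIP photobleaching time series
    into freely diffusing and chromatin-bound pools, and the accompanying
    statistical battery (Shapiro-Wilk gate, Wilcoxon rank-sum with
    Bonferroni correction, Pearson correlation, chi-square independence,
    comparative-Ct fold changes and reporter repression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    igraph,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
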