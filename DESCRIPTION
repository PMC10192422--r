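Package: waveclust
Title: Wavelet Clustering of Microbial Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters densely sampled community time series by the similarity
    of their wavelet spectra rather than by correlations in abundance.
    Provides compositional preprocessing for microbiome count tables (depth
    filtering, core-taxon selection, centered log-ratio transform, monotone
    cubic Hermite interpolation to an equidistant grid, and Box-Cox rescaling
    chosen by the probability-plot correlation coefficient), Morlet continuous
    wavelet transforms with cone-of-influence handling, Markov-surrogate
    significance testing of wavelet power, a maximum-covariance-analysis
    distance between significance-masked spectra, Ward clustering, and
    quantitative dendrogram comparison via the Fowlkes-Mallows Bk statistic
    with asymptotic and permutation null distributions, plus total branch
    length. Includes a synthetic-data module generating oscillatory test
    signals and microbiome-like compositional count tables with known
    ground-truth community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
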