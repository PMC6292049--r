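Package: nbmixclust
Title: Negative Binomial Mixture Clustering of RNA-Seq Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-based unsupervised clustering of samples from
    over-dispersed RNA-seq count matrices using a mixture of Negative
    Binomial distributions fitted by a deterministic-annealing EM
    algorithm with BIC selection of the number of clusters. Includes
    upper-quartile CPM normalization, MAD-based gene filtering, log and
    rank-based inverse-normal (Blom) transforms, a synthetic clustered
    count simulator, Gaussian-mixture comparators, and adjusted Rand
    index benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
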