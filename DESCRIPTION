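Package: spectrofibro
Title: FTIR Spectral Histopathology of Hepatic Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Fourier-transform infrared (FTIR)
    hyperspectral images of paraffin-embedded cirrhotic liver tissue.
    Provides extended multiplicative signal correction (EMSC) for digital
    dewaxing and normalization, per-image and multi-image (common) k-means
    clustering to segment fibrous septa from regeneration nodules,
    Savitzky-Golay second-derivative band analysis of cluster centroids
    with infrared band assignment, Masson's-trichrome color deconvolution
    for reference fibrosis quantification, and the correlation and group
    statistics linking the spectral and histological estimates. A synthetic
    phantom generator produces paired hyperspectral cubes, pure-paraffin
    reference cubes and trichrome renderings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
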