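Package: psuptake
Title: Quantification of Polystyrene Nanoparticle Uptake from Confocal and
    Raman Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-quantitative analysis of fluorescent polystyrene
    nanoparticle uptake by cultured cells from confocal z-stacks
    (bead-pixels-per-cell statistic with dose-response statistics) and
    label-free localization of intracellular polystyrene in Raman
    hyperspectral scans (spike removal, SNIP baseline correction, mean
    normalization, silent-region excision, N-FINDR endmember extraction and
    non-negative least-squares abundance mapping). Includes synthetic-data
    generators with known ground truth for both modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    generics,
    rlang,
    withr,
    EBImage,
    pracma,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
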