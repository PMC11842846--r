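Package: nucmorph
Title: Cell and Nucleus Morphological Heterogeneity in Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell and nucleus morphological heterogeneity in
    epithelial monolayers from paired label masks and intensity channels.
    Provides a synthetic monolayer and division-lineage generator with
    log-normal area and gamma aspect-ratio statistics, per-cell morphometric
    feature extraction with edge and mitotic exclusion rules, mean-normalized
    distribution collapse with log-normal and unit-mean gamma maximum
    likelihood fits, nucleus-cell coordination statistics with Fisher-z
    confidence intervals and Monte Carlo permutation false discovery rates,
    radial chromatin-mark statistics based on a distance-transform
    periphery/center split, and a multivariable prediction stack (linear,
    squared-exponential kernel, canonical correlation, principal components,
    dropout feature importance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
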