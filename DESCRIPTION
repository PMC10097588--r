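Package: cellspring
Title: Deconvolution of Single-Cell Stiffness into Subcellular Spring Contributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes single-cell indentation force curves (micro-indentation
    and AFM dialects) into per-cell stiffness, Hertz indentation modulus and
    dissipated-energy measurements, and deconvolutes treatment-level stiffness
    into cell-wall, protoplasm, microtubule and actin-filament contributions
    with a series-parallel spring network. Parameters are estimated by
    constrained maximum a posteriori optimisation of a weighted Gaussian
    objective with Laplace-approximation credible intervals, with an optional
    combined analysis that carries AFM-derived cell-wall stiffness ratios into
    the spring equations. Includes empirical-CDF and two-sample
    Kolmogorov-Smirnov comparison utilities and a seeded synthetic-data
    generator for end-to-end validation.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
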