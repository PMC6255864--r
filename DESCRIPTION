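Package: heightspec
Title: High-Speed AFM Height Spectroscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for high-speed atomic force microscopy (HS-AFM)
    height spectroscopy and line scanning of membrane proteins. Converts
    height/time traces into single-molecule diffusion events, dwell-time
    distributions with multi-Gaussian deconvolution, diffusion coefficients,
    surface concentrations, two-dimensional oligomerization equilibria
    (dissociation constants, equilibrium oligomer distributions, free
    energies), and two-state rotation statistics from telegraph traces and
    line-scan kymographs. Includes a physics-based synthetic-data generator
    (Brownian diffusion under a tip detection disk, z-feedback surrogate,
    telegraph and kymograph models) so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
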