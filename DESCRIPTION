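Package: spherowave
Title: Mechanistic PDE Modeling of Tumor Spheroid Growth and Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates radially symmetric reaction-diffusion-advection
    models of multicellular tumor spheroid growth and invasion, fits them
    to radial cell-density time series by global (DIRECT) plus local
    least-squares optimization, compares model variants by the
    least-squares Akaike information criterion, characterizes intra-tumor
    heterogeneity through numerically estimated wave-front speeds, and
    classifies cell lines as Go-or-Grow phenotypes. Includes a synthetic
    data module (density series and spheroid-like images) and an image
    processing pipeline that converts brightfield-style spheroid images
    into radial density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    data.table,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
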