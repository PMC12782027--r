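Package: lipidxr
Title: Liquid-Surface X-Ray Reflectivity Analysis of Lipid Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and inversion of specular X-ray reflectivity
    from Langmuir lipid monolayers at the air/water interface. Computes
    reflectivity from slab (box) models of the electron-density profile via
    the Parratt recursion with error-function interfacial roughness, fits
    two-layer (tails/headgroups) models to Fresnel-normalized data by bounded
    multi-start least squares with finite-difference covariance errors, and
    performs model-independent electron-density inversion with cubic
    B-splines, reporting the family of profiles within 20 percent of the
    minimum chi-square as uncertainty ribbons. Includes a synthetic-data
    generator for enzyme-oxidation experiments on SAPC, DSPC and PAzePC
    monolayers and derives oxidation-induced structural metrics such as
    lipid-tail shortening and headgroup density changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    splines,
    stats,
    utils,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
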