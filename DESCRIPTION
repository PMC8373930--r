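Package: stabfit
Title: Two-State Protein Stability from Joint Thermal and Chemical Denaturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Global analysis of two-dimensional (temperature by denaturant)
    equilibrium unfolding fluorescence data under a two-state folding model.
    Folding free energies follow the Gibbs-Helmholtz relation in temperature
    and the linear extrapolation method in denaturant concentration. Provides
    weighted least-squares global fits of melting curves across denaturant
    series with shared or fixed m-values, delta-method standard errors for
    derived quantities (free energy of folding, unfolding midpoints, apparent
    melting temperatures), double-mutant-cycle coupling energies with
    quadrature error propagation, a seeded synthetic-data generator matching
    the nanoDSF experimental design, and a packaged table of fitted
    thermodynamic parameters for 26 variants of chymotrypsin inhibitor 2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    withr
Config/testthat/edition: 3
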