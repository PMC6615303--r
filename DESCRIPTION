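Package: pepperphys
Title: Photosynthesis, Isotope Discrimination and Leaching-Fraction Water
    Balance for Salinity Pot Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for factorial pot experiments on irrigation-water
    salinity and leaching fraction in hot pepper (Capsicum annuum).  Provides
    forward evaluation and bounded nonlinear least-squares fitting of the
    non-rectangular-hyperbola light-response model and the rectangular-hyperbola
    CO2-response model, carbon and nitrogen stable-isotope metrics (delta13C,
    delta15N, Delta13C discrimination, elemental accumulation), the pot
    weighing water balance with leaching-fraction scheduling and seasonal
    accounting, derived leaf gas-exchange metrics (intrinsic water-use
    efficiency, Ci/Ca, percent change, the log-linear Pn-gs relationship),
    two-way factorial ANOVA with Duncan's multiple-range letters and ANCOVA
    slope-homogeneity tests, and a synthetic-experiment generator that emulates
    a 3 x 2 x 4 salinity-by-leaching design so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
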