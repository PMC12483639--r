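Package: oncotip
Title: Extinction-Threshold Models of Cancer Development and Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic models of cancer development built
    around an emergent extinction threshold: generalized logistic (Richards)
    growth and two threshold extensions, linear stability analysis and the
    growth/saturation asymmetry ratio, a binomial daily mutation process with
    an age-increasing mutation probability, a daily-step stochastic
    carcinogenesis simulator with a moving extinction threshold modulated by
    the menstrual cycle, menopause and hormone replacement therapy,
    Monte-Carlo estimation of age-specific cumulative cancer risk, and
    shooting-based least-squares fitting of the growth models to tumour
    time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
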