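Package: capmoist
Title: Capacitive Grain Moisture Modelling with Chaos-Initialised Sparrow Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating grain (foxtail millet) moisture content from
    parallel-plate capacitance measurements. Implements a closed-form
    dielectric mixing model with exact analytic inverse, the sparrow search
    algorithm (SSA) and its logistic-chaos-initialised variant (LCSSA) for
    bound-constrained optimisation, extreme learning machine (ELM) and
    back-propagation (BP) regressors with metaheuristic weight tuning, the
    R/RMSE/RPD evaluation metric suite with reliability bands, a synthetic
    generator emulating a factorial capacitance measurement campaign, and an
    end-to-end reproducible pipeline comparing the six model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
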