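Package: idhale
Title: Life Expectancy and Health-Adjusted Life Expectancy via Sullivan
    Life Tables and Illness-Death Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates life expectancy (LE) and health-adjusted life
    expectancy (HALE) for a chronic disease in an elderly population by two
    complementary routes: Chiang abridged life tables combined with
    Sullivan prevalence weighting, and a three-state illness-death
    continuous-time Markov model fitted by maximum likelihood to
    interval-censored two-wave panel data, with total and state-specific
    life expectancies obtained by numerical integration of the transition
    probabilities. A synthetic-cohort generator simulates elderly cohorts
    from known Gompertz transition intensities (burn-in onset, exact death
    ages, interval-censored incidence, loss to follow-up) so that every
    stage of the pipeline can be validated against closed-form and
    simulation oracles without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
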