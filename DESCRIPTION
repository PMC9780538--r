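Package: awaremdp
Title: Awareness Dynamics as a Finite-Horizon Markov Decision Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a dual-process model of awareness raising framed as
    a finite-horizon Markov decision process. A scalar awareness state on a
    discrete grid evolves under a birth/stay/death kernel whose forward
    probability mixes analytical and intuitive reasoning curves according to
    an individual's reasoning propensity. Decision policies are either
    habitual (state-independent Gaussian noise around the propensity) or
    self-aware (computed by stochastic dynamic programming with
    direction-weighted Bellman backups), optionally with a state- and
    time-dependent emotional discount factor. Provides Monte Carlo ensemble
    simulation with reproducible seeding, exact distribution propagation and
    exhaustive-enumeration oracles for validation, tidy results, broom-style
    tidiers, and ggplot2 visualisations.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
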