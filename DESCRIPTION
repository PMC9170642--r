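Package: moabattery
Title: Simulation and Psychometrics for the Multiple Object Avoidance Task Battery
Version: 0.1.0
Authors@R: person("MOA", "Battery Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Deterministic, headless re-implementations of a visuomotor
    attention task battery: the Multiple Object Avoidance (MOA) task, a
    Multiple Object Tracking (MOT) task and a Digit Symbol Substitution Test
    (DSST), together with parametric synthetic agents (reaction latency,
    pointer-speed caps, motor noise, tracking capacity), a synthetic-cohort
    generator with designed group effects, and the psychometric analysis
    toolkit typically applied to such scores (hierarchical OLS with nested
    model F-change, Pearson and paired-t reliability reports, one-way ANOVA,
    empirical-logit transforms, and a Pillai-trace multivariate group test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
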