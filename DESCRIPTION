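Package: mptsource
Title: Multidimensional Source-Memory MPT Models with Hierarchical
    Bayesian Latent-Trait Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting the multidimensional source-monitoring
    multinomial processing tree (MPT) model, a two-high-threshold
    recognition model extended with two crossed source dimensions
    (veracity: true/false; importance: important/unimportant).  The model
    separates item detection, joint retrieval of both source features,
    independent retrieval of single features, and guessing.  Estimation is
    hierarchical Bayesian via the latent-trait approach: probit-scale
    individual parameters with a multivariate-normal group prior, sampled
    with JAGS.  Includes a synthetic-cohort generator emulating a
    truth-and-importance feedback experiment, posterior-predictive checks
    for mean frequencies (T1) and the across-participant covariance
    structure (T2), posterior contrasts on group-level parameters with
    Bayesian credibility intervals, Remember/Know response coding,
    EQN export, and a reproducible simulate-fit-check-contrast pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
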