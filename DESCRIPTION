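Package: cfgeom
Title: Counterfactual Geometry and Adversarial Regulation of Future Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-geometric measures (Shannon entropy, Kullback-Leibler
    divergence, Fisher information, credible sets, intervention operators) on
    discrete distributions over future outcomes, together with a minimal
    adversarial Explorer/Verifier saddle-flow model exhibiting collapse,
    bounded-regulation and runaway-sensitivity regimes, trajectory diagnostics
    and a rule-based regime classifier, finite-sample perturbation-response
    proxies with early-warning trend flags, and a one-dimensional
    resource-gated generator/discriminator simulator with finite-sample
    regime diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
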