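Package: cocoaferm
Title: Combinatorial Kinetic Modelling of Cocoa Bean Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanistic analysis of cocoa bean fermentation time
    series. Builds any of 32 coupled ODE model variants describing the
    succession of yeasts, lactic acid bacteria and acetic acid bacteria
    (a 24-parameter baseline plus five optional biochemical mechanisms:
    product decay, fructose use by LAB, acetate production by yeast,
    lactate use by yeast, and acetate over-oxidation by AAB), fits them to
    observed or simulated trials by Bayesian MCMC with truncated weakly
    informative priors, scores variants by PSIS-LOO, pseudo-BMA weights and
    observed/expected success rates, and classifies fermentation features
    (cultivar, method, temperature control, ...) by PCA and pairwise squared
    Mahalanobis distances over posterior parameter draws. Includes a
    synthetic-trial generator emulating literature fermentation datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
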