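Package: hmbmtc
Title: Bayesian Mixed Treatment Comparison of Heavy Menstrual Bleeding Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network meta-analysis (mixed treatment comparison) of treatment
    efficacy for heavy menstrual bleeding. Converts heterogeneous trial-level
    outcome summaries (event counts, mean and standard deviation, median with
    range or quartiles) into proportions of women achieving menstrual blood
    loss below 80 mL (or PBAC score below 100) with standard errors, fits an
    arm-based hierarchical binomial-logit model with study and study-by-class
    random effects, class-by-time effects and a baseline blood-loss covariate
    over a sparse evidence network of eight treatment classes, and summarises
    posterior efficacy per class and follow-up time with 95 percent credible
    intervals. Includes evidence-network connectivity summaries, a blocked
    Metropolis-within-Gibbs sampler with Brooks-Gelman convergence
    diagnostics, and a synthetic-network generator with known ground truth
    for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
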