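Package: metaprl
Title: Belief Volatility, Metacognitive Structure, and Win-Switch Behavior in
    Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and fits a three-level mean-reverting Hierarchical
    Gaussian Filter (HGF) for a three-choice probabilistic reversal learning
    task, scores open-ended self-reflections with a five-dimension
    metacognitive rubric via a pluggable scorer backend, and tests whether
    metacognitive structure attenuates the link between volatility priors and
    win-switch behavior using binomial GLM moderation with bootstrap
    probability-scale contrasts. Includes parameter-recovery and
    volatility-prior grid simulation experiments and a synthetic-cohort
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    lmtest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
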