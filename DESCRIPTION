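Package: physpop
Title: Virtual Human Populations for Physiologically Based
    Pharmacokinetic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical probabilistic simulator of adult human physiology
    for UK and US populations stratified by gender and ethnicity.  Generates
    mutually consistent age, height, body mass, cardiac output and fifteen
    organ and tissue masses and blood flows, with mass balanced to body
    weight and regional flows balanced to cardiac output.  Supports
    conditioning on partial contextual information (exact values or
    intervals for age, height and body mass), aggregation of organs into
    rapidly and slowly perfused compartments, a balance-restoring sink
    update for use inside single-component MCMC samplers, and plausibility
    screening of literature prior specifications against simulated
    reference populations.  Intended as a prior specification for reverse
    dosimetry and quantitative in vitro-to-in vivo extrapolation with PBPK
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    yaml
Config/testthat/edition: 3
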