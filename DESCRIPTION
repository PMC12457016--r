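Package: fissionties
Title: Social Tie Persistence and Group Choice After Primate Group Fission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing which social ties survive a permanent group
    fission in matrilocal primates. Converts raw behavioural observation
    records (focal-follow activity scans, daily census, agonistic
    interactions, birth records, maternal pedigree links) into dyadic
    sociality indices with between-year consistency classes, I&SI ordinal
    dominance hierarchies, maternal relatedness coefficients, reproductive
    state and resident-male tenure. Fits a dyad-level edge-persistence model
    (the dissolution component of a separable temporal exponential random
    graph model under a block-diagonal constraint, which with
    dyad-independent terms reduces to an exact Bernoulli likelihood) and
    conditional-logit models of each female's choice between the two
    daughter groups. Includes a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
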