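Package: kinconflict
Title: Kinship Dynamics and the Inclusive-Fitness Case for Reproductive Cessation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sex- and age-specific local relatedness of female group
    members from demographic parameters (group size, sex-biased dispersal,
    replacement rates, local mating), validates the prediction against an
    individual-based pedigree simulator, estimates observed kinship dynamics
    from dyadic genetic-relatedness data with a Bayesian beta-regression mixed
    model, partitions fission-fusion association data into subgroups by Newman
    modularity, and feeds either predicted or fitted relatedness trajectories
    into an inclusive-fitness threshold model that locates the age at which
    reproductive restraint becomes selectively favoured.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    igraph,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
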