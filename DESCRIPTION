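Package: invasim
Title: Analysis and Simulation of Whole-Community Microbial Invasion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of factorial microbial
    community-invasion (community coalescence) experiments. Provides
    presence/absence classification of OTUs into invasion-outcome categories
    (invader, noninvasive, resilient, nonresilient, common, undetermined)
    with repeated-rarefaction averaging; family-level strong/weak competitor
    scoring; rarefaction, alpha-diversity and Bray-Curtis community metrics;
    multifactorial ANOVA and PERMANOVA with model reduction and estimated
    percent-variance components for partitioning propagule-pressure versus
    biotic-interaction effects; and a synthetic-data generator that emulates
    a two-environment factorial invasion microcosm design with planted
    ground-truth invasion outcomes and known functioning variance shares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
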