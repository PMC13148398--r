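Package: podsim
Title: Forward Simulation of Pseudo-Overdominance in Diploid and
    Autotetraploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of constant-size
    diploid and tetrasomic autotetraploid populations accumulating
    recessive deleterious mutations on a single recombining chromosome.
    Tetraploid meiosis forms random bivalents (all three pairings of the
    four homologues equally likely) with no double reduction. Fitness is
    multiplicative over segregating mutations, with either fully
    recessive constant-effect mutations or an empirical gamma
    distribution of fitness effects with a dominance-selection
    relationship. The package records per-generation trajectories of
    median allele frequency, mean and parental fitness, and segregating
    and fixed mutation counts; classifies runs against four criteria for
    pseudo-overdominance; and drives replicated parameter sweeps over
    mutation rate, recombination rate, selection strength, population
    size and ploidy, aggregated into allele-frequency heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
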