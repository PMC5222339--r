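Package: ramets
Title: Clonal Structure and Population Differentiation from Multilocus Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing partially clonal populations genotyped at
    co-dominant microsatellite loci, motivated by clonal scleractinian corals.
    Discriminates multilocus genotypes (MLG) and collapses them into
    multilocus lineages (MLL) using stepwise-mutation-model distances and a
    gap-derived threshold; computes clonality statistics (P_gen, P_SEX with
    inbreeding, probability of identity, clonal richness R, genotypic
    diversity G, Simpson evenness, the Pareto clone-size exponent, rarefied
    allelic richness); permutation-tested spatial statistics of clonal
    structure (aggregation index, edge effect, Moran's I); Weir-Cockerham
    F-statistics and Jost's D_est on entire and clone-censored datasets;
    Dice-distance principal coordinates and shared-allele clone networks; a
    forward simulator of spatially structured, partially clonal multi-site
    populations with ground truth; and a degree-day phenology comparison for
    paired sea-temperature series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
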