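Package: admixkit
Title: Admixture Simulation, Ancestry-Specific IBD Demography, and
    Map-Aware Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how recombination-map choice and admixture
    history propagate through downstream population-genetic analyses.
    Provides a forward-time admixture simulator with truth local-ancestry
    tracts and truth identity-by-descent (IBD) segments over
    hotspot-punctuated recombination maps; scoring of inferred local
    ancestry against truth; gap-merging and ancestry assignment of IBD
    segments; recent effective population size estimation from the
    ancestry-specific IBD length spectrum with bootstrap confidence
    intervals; merging of recent and ancient demographic trajectories;
    genetic-map binning, rank-correlation comparison, clustering, and
    hotspot calling; and an integrated haplotype score (iHS) scan
    parameterized by a genetic map, with a two-map sensitivity comparison.
    A config-driven pipeline ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
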