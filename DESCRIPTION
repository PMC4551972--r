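Package: reefconn
Title: Seascape Connectivity Analysis and Simulation-Based Power Tests for
    Reef Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess genetic connectivity of reef-associated marine
    populations from multilocus codominant genotypes and mtDNA haplotypes.
    Implements diversity indices (observed and unbiased expected
    heterozygosity, rarefaction allelic richness, fixation index), the
    standard differentiation estimators (Weir-Cockerham theta, Hedrick's
    G'st, Jost's D, and the standardized F'st obtained by
    maximal-differentiation recoding) with locus-bootstrap confidence
    intervals and permutation tests, and individual-based genotypic spatial
    autocorrelation over membership-defined distance classes with
    permutation null envelopes, pair bootstraps and the nonparametric
    correlogram heterogeneity test.  A forward-time simulator of
    microsatellite evolution on a two-dimensional stepping-stone grid of
    reefs, parameterized from reef demography, provides simulation-based
    power analysis for detecting gene flow, and doubles as the synthetic
    data generator for all statistics.  Genotypes are exchanged in genepop
    format with a sidecar metadata table; haplotypes in FASTA.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    ape,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
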