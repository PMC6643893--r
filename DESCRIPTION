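Package: lasgs
Title: Look-Ahead Selection and Breeding-Program Simulation for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deadline-aware look-ahead selection (LAS) for genomic selection
    breeding programs, built on a Markov-chain model of gamete ancestry under
    recombination, together with the conventional GEBV, weighted-GEBV, optimal
    haploid value (OHV) and optimal population value (OPV) selection criteria.
    Includes a stochastic multi-generation breeding-campaign simulator
    (meiosis with recombination, truncation and group-based selection,
    pairwise-swap simulation optimization with common random numbers,
    diversity-proportional progeny allocation), phased-genotype and genetic-map
    I/O, and a synthetic-scenario generator for reproducible method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
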