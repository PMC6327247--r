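Package: driftwave
Title: F-Statistics, Ancestry-Stream Rank Tests, and Admixture Graph
    Fitting for Pseudo-Haploid Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for allele-frequency-based demographic inference from
    ancient and present-day genotype data in EIGENSTRAT format: f2, f3
    (including outgroup-f3 and the pseudo-haploid "inbreed" bias
    correction), f4 and D statistics with weighted block-jackknife
    standard errors over 5-Mb genomic blocks; a rank test on matrices of
    f4 statistics for the minimum number of ancestry streams relating a
    set of test populations to outgroups; admixture-graph prediction,
    fitting, per-edge jackknife uncertainties and greedy graft search;
    PCA with least-squares projection of low-coverage samples; and MDS /
    neighbor-joining views of shared-drift (outgroup-f3) matrices.  A
    companion simulator generates pseudo-haploid genotype datasets by
    drifting allele frequencies down a known admixture graph, so that
    every stage of the pipeline can be exercised and calibrated on data
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
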