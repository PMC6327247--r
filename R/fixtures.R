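# Canned simulation scenarios ("fixtures") mirroring the demographic
# structures the analysis stack is designed to detect: a single ancestry
# stream, two and three differentiated streams, a star-like radiation, and
# a star with one extra lineage contributing to a subset of leaves.

de <- function(parent, child, value)
  data.frame(parent = parent, child = child, type = "drift", value = value,
             free = TRUE)
am <- function(parent, child, alpha)
  data.frame(parent = parent, child = child, type = "admix", value = alpha,
             free = TRUE)

#' Canned admixture-graph topologies
#'
#' Returns one of the graphs underlying [make_fixture()].  In addition to
#' the five fixture scenarios, two graphs used for parameter-recovery
#' exercises are available: `"alpha_recovery"` (six leaves, one admixture
#' event with proportion 0.3, drift lengths between 5 and 50 units) and
#' `"zero_edge"` (an admixture source whose private drift edge has true
#' length zero, so that shared drift between the source and its sister
#' leaf is absent by construction).
#'
#' @param name graph name; see Details.
#' @return An [admixture_graph()].
#' @export
fixture_graph <- function(name) {
  switch(name,
    single_wave = admixture_graph(rbind(
      de("root", "O", 100),
      de("root", "m1", 20), de("m1", "R1", 50),
      de("m1", "m2", 20), de("m2", "R2", 50),
      de("m2", "m3", 20), de("m3", "R3", 50),
      de("m3", "m4", 20), de("m4", "R4", 50),
      de("m4", "m5", 20), de("m5", "R5", 50),
      de("m5", "stem", 20),
      de("stem", "L1", 10), de("stem", "L2", 10), de("stem", "L3", 10))),
    two_wave = admixture_graph(rbind(
      de("root", "O", 100),
      de("root", "x0", 20), de("x0", "R1", 50),
      de("x0", "x1", 20), de("x1", "R2", 50),
      de("x1", "x2", 20),
      de("x2", "a", 40), de("a", "R3", 40), de("a", "s1", 40),
      de("x2", "b", 40), de("b", "R4", 40), de("b", "s2", 40),
      de("s1", "L1", 10),
      am("s1", "mix", 0.6), am("s2", "mix", 0.4), de("mix", "L2", 10))),
    three_source = admixture_graph(rbind(
      de("root", "O", 100),
      de("root", "n1", 20), de("n1", "R1", 50),
      de("n1", "n2", 20), de("n2", "R2", 50),
      de("n2", "n3", 20), de("n3", "R3", 50),
      de("n3", "n4", 20),
      de("n4", "u", 60), de("u", "R4", 50), de("u", "s2", 40),
      de("n4", "w", 60), de("w", "RD", 50), de("w", "s3", 40),
      de("n4", "stem", 10), de("stem", "T1", 10),
      am("stem", "m2", 0.6), am("s2", "m2", 0.4), de("m2", "T2", 10),
      am("stem", "m3", 0.6), am("s3", "m3", 0.4), de("m3", "T3", 10))),
    star_radiation = admixture_graph(rbind(
      de("root", "O", 100),
      de("root", "c0", 30),
      de("c0", "L1", 20), de("c0", "L2", 20), de("c0", "L3", 20),
      de("c0", "L4", 20), de("c0", "L5", 20))),
    anzick_affinity_toy = admixture_graph(rbind(
      de("root", "O", 100),
      de("root", "m1", 20), de("m1", "U", 50),
      de("m1", "m2", 20),
      de("m2", "az0", 30), de("az0", "ANZ", 30), de("az0", "zsrc", 10),
      de("m2", "stem", 20),
      de("stem", "L1", 15), de("stem", "L2", 15), de("stem", "L3", 15),
      am("stem", "q4", 0.7), am("zsrc", "q4", 0.3), de("q4", "L4", 15),
      am("stem", "q5", 0.7), am("zsrc", "q5", 0.3), de("q5", "L5", 15))),
    alpha_recovery = admixture_graph(rbind(
      de("root", "O", 50),
      de("root", "p1", 10),
      de("p1", "pa", 10), de("pa", "A", 40), de("pa", "sa", 10),
      de("p1", "p2", 30), de("p2", "B", 40),
      de("p2", "p3", 30), de("p3", "C", 40),
      de("p3", "pd", 10), de("pd", "D", 40), de("pd", "sd", 10),
      am("sa", "mm", 0.3), am("sd", "mm", 0.7), de("mm", "M", 10))),
    tree6 = admixture_graph(rbind(
      de("root", "O", 50),
      de("root", "p1", 10),
      de("p1", "pa", 10), de("pa", "A", 40),
      de("p1", "p2", 30), de("p2", "B", 40),
      de("p2", "p3", 30), de("p3", "C", 40),
      de("p3", "pd", 10), de("pd", "D", 40),
      de("pd", "sd", 10), de("sd", "M", 10))),
    zero_edge = admixture_graph(rbind(
      de("root", "O", 60),
      de("root", "n1", 10), de("n1", "U", 40),
      de("n1", "n2", 10),
      de("n2", "a0", 5), de("a0", "A", 30), de("a0", "a1", 5),
      de("n2", "b", 0), de("b", "K", 30),
      am("a1", "m", 0.7), am("b", "m", 0.3), de("m", "M", 10))),
    stopf("unknown graph '%s'; valid names: %s", name,
          paste(c("single_wave", "two_wave", "three_source",
                  "star_radiation", "anzick_affinity_toy",
                  "alpha_recovery", "zero_edge", "tree6"), collapse = ", ")))
}

FIXTURE_NAMES <- c("single_wave", "two_wave", "three_source",
                   "star_radiation", "anzick_affinity_toy")

#' Generate a canned simulated dataset with known truth
#'
#' Simulates allele frequencies down one of the fixture graphs and samples
#' a genotype dataset from them.  The default sampling conditions emulate
#' a desk-scale ancient-DNA panel: the outgroup `O` is a diploid panel of
#' 10 individuals with 2% missingness; every other population consists of
#' 5 pseudo-haploid individuals with 20% missing entries.
#'
#' @param name one of `"single_wave"`, `"two_wave"`, `"three_source"`,
#'   `"star_radiation"`, `"anzick_affinity_toy"`.
#' @param seed master integer seed; the same `(name, seed)` always returns
#'   an identical dataset.
#' @param n_snps number of SNPs (default 20000).
#' @param ... further arguments passed to [simulation_scenario()],
#'   overriding the fixture defaults.
#' @return A list with elements `dataset` (a [genotype_dataset()]),
#'   `freq_table` (true leaf frequencies), `truth` (the truth record) and
#'   `scenario`.
#' @export
make_fixture <- function(name, seed, n_snps = 20000, ...) {
  if (!name %in% FIXTURE_NAMES)
    stopf("unknown fixture '%s'; valid names: %s", name,
          paste(FIXTURE_NAMES, collapse = ", "))
  graph <- fixture_graph(name)
  scenario <- fixture_scenario(graph, seed, n_snps, ...)
  sim <- simulate_frequencies(scenario)
  dataset <- sample_genotypes(sim$freq_table, scenario)
  list(dataset = dataset, freq_table = sim$freq_table, truth = sim$truth,
       scenario = scenario)
}

# Default sampling conditions for fixture graphs (outgroup "O" diploid if
# present, ancients pseudo-haploid).
fixture_scenario <- function(graph, seed, n_snps, ...) {
  leaves <- graph$leaves
  ploidy <- setNames(rep("pseudo_haploid", length(leaves)), leaves)
  nsamp <- setNames(rep(5L, length(leaves)), leaves)
  miss <- setNames(rep(0.2, length(leaves)), leaves)
  if ("O" %in% leaves) {
    ploidy[["O"]] <- "diploid"; nsamp[["O"]] <- 10L; miss[["O"]] <- 0.02
  }
  args <- list(graph = graph, n_snps = n_snps, samples_per_pop = nsamp,
               ploidy = ploidy, missing_rate = miss, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_scenario, args)
}
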