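# Simulation of allele frequencies down an admixture graph and of
# pseudo-haploid / diploid genotype fixtures with known truth.
#
# Drift along an edge of length c (F_ST x 1000 units) is a Balding-Nichols
# beta draw: the child frequency has mean p (the parent frequency) and
# variance (c/1000) * p * (1 - p).  Frequencies fixed at 0 or 1 stay
# fixed.  At an admixture node with parents (u, v) and proportion alpha,
# the frequency is alpha * p_u + (1 - alpha) * p_v exactly.  In the
# small-drift regime these choices make expected f2 between two leaves
# additive in the path drift, matching the units in which graph edge
# lengths are expressed.

# 22 autosomes of 125 Mb each: enough physical span for ~550 5-Mb
# jackknife blocks regardless of the simulated SNP count.
default_chromosome_layout <- function() {
  data.frame(label = as.character(1:22), length = rep(125e6, 22))
}

#' Describe a simulation scenario
#'
#' Collects every knob of the genotype simulator.  The defaults emulate
#' the study conditions of a 1240k-style pseudo-haploid ancient-DNA panel
#' at desk scale: a few pseudo-haploid individuals per ancient group, a
#' larger diploid outgroup panel, moderate per-entry missingness, and a
#' transition-rich SNP map laid out over 22 autosomes.
#'
#' @param graph an [admixture_graph()]; its leaves are the populations.
#' @param n_snps number of SNPs to simulate.
#' @param root_freq_law length-2 numeric, the ancestral frequency is drawn
#'   uniformly on this interval (away from the boundaries, approximating
#'   capture-panel ascertainment).
#' @param samples_per_pop named integer vector (leaf -> count) or a single
#'   count applied to every leaf.
#' @param ploidy named character vector (leaf -> `"diploid"` or
#'   `"pseudo_haploid"`) or a single mode for all leaves.
#' @param missing_rate named numeric vector (leaf -> rate) or single rate;
#'   each genotype entry is independently set missing with this
#'   probability.
#' @param transition_fraction fraction of SNPs flagged as transitions
#'   (A/G or C/T allele pairs).
#' @param chromosome_layout data frame with columns `label` and `length`
#'   (bp); SNP positions are uniform within chromosomes, then sorted.
#' @param seed master integer seed; each simulator operation draws from a
#'   sub-seeded stream so stages are individually reproducible.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(graph, n_snps = 50000,
                                root_freq_law = c(0.05, 0.95),
                                samples_per_pop = 5L,
                                ploidy = "pseudo_haploid",
                                missing_rate = 0.1,
                                transition_fraction = 2 / 3,
                                chromosome_layout = default_chromosome_layout(),
                                seed = 1L) {
  stopifnot(inherits(graph, "admixture_graph"))
  leaves <- graph$leaves
  expand <- function(x, default_names = leaves) {
    if (is.null(names(x))) {
      if (length(x) != 1L) stopf("per-population settings must be named")
      x <- rep(x, length(default_names)); names(x) <- default_names
    } else {
      miss <- setdiff(default_names, names(x))
      if (length(miss)) stopf("missing per-population setting for: %s",
                              paste(miss, collapse = ", "))
      x <- x[default_names]
    }
    x
  }
  samples_per_pop <- expand(samples_per_pop)
  ploidy <- expand(ploidy)
  missing_rate <- expand(missing_rate)
  if (any(missing_rate < 0 | missing_rate > 1)) stopf("missing_rate must be in [0,1]")
  if (transition_fraction < 0 || transition_fraction > 1)
    stopf("transition_fraction must be in [0,1]")
  if (any(chromosome_layout$length <= 0)) stopf("chromosome lengths must be positive")
  structure(list(graph = graph, n_snps = as.integer(n_snps),
                 root_freq_law = root_freq_law,
                 samples_per_pop = samples_per_pop, ploidy = ploidy,
                 missing_rate = missing_rate,
                 transition_fraction = transition_fraction,
                 chromosome_layout = chromosome_layout,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Random SNP map consistent with the scenario's chromosome layout.
simulate_snp_map <- function(scenario) {
  n <- scenario$n_snps
  lay <- scenario$chromosome_layout
  chrom_idx <- sample.int(nrow(lay), n, replace = TRUE,
                          prob = lay$length / sum(lay$length))
  pos <- 1L + as.integer(floor(runif(n) * (lay$length[chrom_idx] - 1)))
  ord <- order(chrom_idx, pos)
  chrom_idx <- chrom_idx[ord]; pos <- pos[ord]
  is_ts <- runif(n) < scenario$transition_fraction
  a1 <- ifelse(is_ts, "A", "A")
  a2 <- ifelse(is_ts, "G", "C")
  data.frame(snp_id = sprintf("snp%06d", seq_len(n)),
             chrom = lay$label[chrom_idx], genetic_pos = 0,
             physical_pos = pos, allele1 = a1, allele2 = a2,
             stringsAsFactors = FALSE)
}

#' Simulate true leaf allele frequencies down an admixture graph
#'
#' @param scenario a [simulation_scenario()].
#' @return A list with `freq_table` (a [freq_table()] of the true leaf
#'   frequencies, with infinite counts, plus the simulated SNP map) and
#'   `truth` (a truth record holding the graph, scenario parameters and
#'   per-edge realized F_ST).
#' @export
simulate_frequencies <- function(scenario) {
  graph <- scenario$graph
  with_seed(sub_seed(scenario$seed, 1L), {
    snp <- simulate_snp_map(scenario)
    n <- scenario$n_snps
    e <- graph$edges
    p <- matrix(NA_real_, length(graph$nodes), n,
                dimnames = list(graph$nodes, NULL))
    p[graph$root, ] <- runif(n, scenario$root_freq_law[1],
                             scenario$root_freq_law[2])
    realized <- numeric(nrow(e))
    for (v in graph$nodes[-1]) {
      inc <- which(e$child == v)
      if (length(inc) == 1L && e$type[inc] == "drift") {
        pp <- p[e$parent[inc], ]
        f <- e$value[inc] / 1000
        if (f <= 0) {
          pc <- pp
        } else {
          a <- pp * (1 - f) / f
          b <- (1 - pp) * (1 - f) / f
          pc <- rbeta(n, a, b)
          fixed <- pp <= 0 | pp >= 1
          pc[fixed] <- pp[fixed]
        }
        p[v, ] <- pc
        poly <- pp > 0 & pp < 1
        realized[inc] <- mean((pc - pp)[poly]^2) / mean((pp * (1 - pp))[poly])
      } else {
        # admixture node: exact frequency mixture
        pu <- p[e$parent[inc[1]], ]; pv <- p[e$parent[inc[2]], ]
        p[v, ] <- e$value[inc[1]] * pu + e$value[inc[2]] * pv
      }
    }
    freqs <- p[graph$leaves, , drop = FALSE]
    ft <- freq_table(pops = graph$leaves, freq = freqs,
                     count = matrix(Inf, nrow(freqs), ncol(freqs)),
                     snp = snp)
    truth <- structure(list(graph = graph, scenario = scenario,
                            realized_fst = data.frame(
                              parent = e$parent, child = e$child,
                              type = e$type, value = e$value,
                              realized_fst = realized)),
                       class = "simulation_truth")
    list(freq_table = ft, truth = truth)
  })
}

#' Sample genotypes from true population frequencies
#'
#' Diploid samples draw two binomial alleles per site; pseudo-haploid
#' samples draw one allele, coded 0/2.  Each entry is then independently
#' set missing at the population's missing rate.
#'
#' @param freq_table the true-frequency table from
#'   [simulate_frequencies()] (same scenario).
#' @param scenario the matching [simulation_scenario()].
#' @return A [genotype_dataset()] whose group labels are the graph leaves.
#' @export
sample_genotypes <- function(freq_table, scenario) {
  with_seed(sub_seed(scenario$seed, 2L), {
    n <- ncol(freq_table$freq)
    pops <- freq_table$pops
    mats <- list(); samp <- list()
    for (pop in pops) {
      k <- scenario$samples_per_pop[[pop]]
      if (k < 1L) next
      f <- freq_table$freq[pop, ]
      ph <- scenario$ploidy[[pop]] == "pseudo_haploid"
      fm <- matrix(rep(f, each = k), k, n)
      g <- if (ph) 2L * matrix(rbinom(k * n, 1L, fm), k, n)
           else matrix(rbinom(k * n, 2L, fm), k, n)
      mr <- scenario$missing_rate[[pop]]
      if (mr > 0) g[matrix(runif(k * n) < mr, k, n)] <- NA_integer_
      mats[[pop]] <- g
      samp[[pop]] <- data.frame(
        sample_id = sprintf("%s_%d", pop, seq_len(k)), sex = "U",
        group_label = pop, regional_label = NA_character_,
        ploidy_mode = if (ph) "pseudo_haploid" else "diploid",
        stringsAsFactors = FALSE)
    }
    genotype_dataset(freq_table$snp, do.call(rbind, samp),
                     do.call(rbind, mats))
  })
}

#' Write / read a simulation truth record
#'
#' Serializes the generating graph, every scenario parameter and the
#' per-edge realized F_ST to a plain-text file, with 17 significant digits
#' so the round trip is lossless; re-simulating from a reloaded record
#' reproduces the dataset exactly.
#'
#' @param truth a truth record from [simulate_frequencies()].
#' @param path file path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   record.
#' @export
write_truth <- function(truth, path) {
  sc <- truth$scenario
  num <- function(x) sprintf("%.17g", x)
  lines <- c("# driftwave simulation truth v1", "[graph]")
  e <- truth$graph$edges
  lines <- c(lines, sprintf("%s %s %s %s %s", e$type, e$parent, e$child,
                            num(e$value), ifelse(e$free, "free", "fixed")))
  lines <- c(lines, "[scenario]",
             paste("n_snps", sc$n_snps),
             paste("seed", sc$seed),
             paste("root_freq_law", num(sc$root_freq_law[1]), num(sc$root_freq_law[2])),
             paste("transition_fraction", num(sc$transition_fraction)))
  lines <- c(lines, "[populations]",
             sprintf("%s %d %s %s", names(sc$samples_per_pop),
                     sc$samples_per_pop, sc$ploidy, num(sc$missing_rate)))
  lines <- c(lines, "[chromosomes]",
             sprintf("%s %s", sc$chromosome_layout$label,
                     num(sc$chromosome_layout$length)))
  lines <- c(lines, "[realized_fst]",
             sprintf("%s %s %s", truth$realized_fst$parent,
                     truth$realized_fst$child, num(truth$realized_fst$realized_fst)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  sec <- cumsum(startsWith(lines, "["))
  name <- sub("\\[(.*)\\]", "\\1", lines[startsWith(lines, "[")])
  body <- split(lines[!startsWith(lines, "[")],
                name[sec[!startsWith(lines, "[")]])
  sp <- function(v) strsplit(v, " ", fixed = TRUE)
  ge <- do.call(rbind, sp(body$graph))
  graph <- admixture_graph(data.frame(
    parent = ge[, 2], child = ge[, 3], type = ge[, 1],
    value = as.numeric(ge[, 4]), free = ge[, 5] == "free"))
  kv <- do.call(rbind, lapply(sp(body$scenario), function(x)
    c(x[1], paste(x[-1], collapse = " "))))
  get <- function(k) kv[kv[, 1] == k, 2]
  pp <- do.call(rbind, sp(body$populations))
  lay <- do.call(rbind, sp(body$chromosomes))
  rf <- do.call(rbind, sp(body$realized_fst))
  scenario <- simulation_scenario(
    graph, n_snps = as.integer(get("n_snps")),
    root_freq_law = as.numeric(strsplit(get("root_freq_law"), " ")[[1]]),
    samples_per_pop = setNames(as.integer(pp[, 2]), pp[, 1]),
    ploidy = setNames(pp[, 3], pp[, 1]),
    missing_rate = setNames(as.numeric(pp[, 4]), pp[, 1]),
    transition_fraction = as.numeric(get("transition_fraction")),
    chromosome_layout = data.frame(label = lay[, 1],
                                   length = as.numeric(lay[, 2])),
    seed = as.integer(get("seed")))
  truth <- structure(list(graph = graph, scenario = scenario,
                          realized_fst = data.frame(
                            parent = rf[, 1], child = rf[, 2],
                            realized_fst = as.numeric(rf[, 3]))),
                     class = "simulation_truth")
  truth
}
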