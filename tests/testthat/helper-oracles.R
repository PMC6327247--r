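# Independent brute-force oracles used to validate the vectorized
# estimators.  These deliberately loop SNP by SNP / block by block with
# scalar arithmetic and share no code with the package internals.

# Naive f-statistic: mean per-SNP summand (or ratio of sums for D) over
# the SNPs where every involved population has data.
oracle_fstat <- function(ft, kind, pops, inbreed = TRUE) {
  S <- ncol(ft$freq)
  num <- 0; den <- 0; used <- 0
  hterm <- function(p, n) if (!is.finite(n)) 0 else p * (1 - p) / (n - 1)
  for (s in seq_len(S)) {
    p <- ft$freq[pops, s]; n <- ft$count[pops, s]
    if (any(n <= 0)) next
    if (kind == "f2") {
      if (inbreed && any(n < 2 & is.finite(n))) next
      v <- (p[1] - p[2])^2
      if (inbreed) v <- v - hterm(p[1], n[1]) - hterm(p[2], n[2])
      num <- num + v
    } else if (kind == "f3") {
      if (inbreed && n[1] < 2 && is.finite(n[1])) next
      v <- (p[1] - p[2]) * (p[1] - p[3])
      if (inbreed) v <- v - hterm(p[1], n[1])
      num <- num + v
    } else if (kind == "f4") {
      num <- num + (p[1] - p[2]) * (p[3] - p[4])
    } else if (kind == "D") {
      num <- num + (p[1] - p[2]) * (p[3] - p[4])
      den <- den + (p[1] + p[2] - 2 * p[1] * p[2]) *
        (p[3] + p[4] - 2 * p[3] * p[4])
    }
    used <- used + 1
  }
  unname(if (kind == "D") num / den else num / used)
}

# Naive weighted block jackknife: recomputes every leave-one-out estimate
# from scratch and applies Busing's variance formula term by term.
oracle_jackknife <- function(block_sums, block_weights) {
  g <- length(block_sums)
  n <- sum(block_weights)
  est <- sum(block_sums) / n
  loo <- numeric(g)
  for (j in seq_len(g)) {
    s <- 0; w <- 0
    for (i in seq_len(g)) if (i != j) {
      s <- s + block_sums[i]; w <- w + block_weights[i]
    }
    loo[j] <- s / w
  }
  theta_j <- g * est
  for (j in seq_len(g)) theta_j <- theta_j - (1 - block_weights[j] / n) * loo[j]
  v <- 0
  for (j in seq_len(g)) {
    h <- n / block_weights[j]
    tau <- h * est - (h - 1) * loo[j]
    v <- v + (tau - theta_j)^2 / (h - 1)
  }
  list(estimate = est, se = sqrt(v / g), loo = loo)
}

# Exhaustive path enumeration: all root-to-leaf paths with their
# probabilities, giving per-edge traversal weights independently of the
# package's upward propagation.
oracle_leaf_weights <- function(graph) {
  e <- graph$edges
  drift <- which(e$type == "drift")
  enames <- paste0(e$parent[drift], "->", e$child[drift])
  out <- matrix(0, length(graph$leaves), length(drift),
                dimnames = list(graph$leaves, enames))
  walk <- function(node, prob, edges_taken) {
    inc <- which(e$child == node)
    if (!length(inc)) {          # reached the root
      for (i in edges_taken)
        out[leaf, paste0(e$parent[i], "->", e$child[i])] <<-
          out[leaf, paste0(e$parent[i], "->", e$child[i])] + prob
      return(invisible())
    }
    for (i in inc) {
      pr <- if (e$type[i] == "admix") prob * e$value[i] else prob
      walk(e$parent[i], pr,
           if (e$type[i] == "drift") c(edges_taken, i) else edges_taken)
    }
  }
  for (leaf in graph$leaves) walk(leaf, 1, integer(0))
  out
}

oracle_expected_f2 <- function(graph, a, b) {
  w <- oracle_leaf_weights(graph)
  ce <- graph$edges$value[graph$edges$type == "drift"]
  sum((w[a, ] - w[b, ])^2 * ce)
}

# A complete random frequency table (finite counts, no missing data).
random_freq_table <- function(n_pops, n_snps, seed, count = 20) {
  set.seed(seed)
  pops <- paste0("P", seq_len(n_pops))
  counts <- matrix(count, n_pops, n_snps)
  a <- matrix(rbinom(n_pops * n_snps, count, runif(n_pops * n_snps, 0.1, 0.9)),
              n_pops, n_snps)
  snp <- data.frame(snp_id = paste0("s", seq_len(n_snps)), chrom = "1",
                    genetic_pos = 0, physical_pos = seq_len(n_snps) * 50000L,
                    allele1 = "A", allele2 = "C")
  freq_table(pops, a / counts, counts, snp)
}

# Procrustes distance after optimal rotation/reflection/translation.
procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Y, X))
  R <- sv$u %*% t(sv$v)
  max(abs(Y %*% R - X))
}

# Standard fixture sampling conditions for an arbitrary graph (outgroup
# "O" diploid panel, others pseudo-haploid), mirroring make_fixture.
graph_scenario <- function(graph, seed, n_snps, ...) {
  lv <- graph$leaves
  simulation_scenario(
    graph, n_snps = n_snps,
    samples_per_pop = setNames(ifelse(lv == "O", 10L, 5L), lv),
    ploidy = setNames(ifelse(lv == "O", "diploid", "pseudo_haploid"), lv),
    missing_rate = setNames(ifelse(lv == "O", 0.02, 0.2), lv),
    seed = seed, ...)
}

simulate_dataset <- function(graph, seed, n_snps, ...) {
  sc <- graph_scenario(graph, seed, n_snps, ...)
  sim <- simulate_frequencies(sc)
  list(dataset = sample_genotypes(sim$freq_table, sc),
       freq = sim$freq_table, scenario = sc, truth = sim$truth)
}

swap_leaves <- function(graph, a, b) {
  e <- graph$edges
  e$child[e$child == a] <- "..tmp.."
  e$child[e$child == b] <- a
  e$child[e$child == "..tmp.."] <- b
  admixture_graph(e)
}

# Expected raw-unit f-statistic for a pure tree under the simulator's
# drift law, edge by edge: each drift edge contributes
# F_e * E[h at its parent], where E[h] attenuates by (1 - F) per
# ancestral edge from E[p0(1-p0)] at the root (exact for the
# Balding-Nichols law; tree graphs only).
oracle_raw_expectation <- function(graph, kind, pops, h0 = 0.1825) {
  e <- graph$edges
  stopifnot(all(e$type == "drift"))
  parent_of <- setNames(e$parent, e$child)
  len_of <- setNames(e$value, e$child)
  att <- vapply(seq_len(nrow(e)), function(i) {
    node <- e$parent[i]; f <- 1
    while (node != graph$root) {
      f <- f * (1 - len_of[[node]] / 1000)
      node <- parent_of[[node]]
    }
    f
  }, 0)
  ce <- e$value / 1000 * att * h0
  w <- leaf_edge_weights(graph)
  e2 <- function(a, b) sum((w[a, ] - w[b, ])^2 * ce)
  switch(kind,
    f2 = e2(pops[1], pops[2]),
    f3 = (e2(pops[1], pops[2]) + e2(pops[1], pops[3]) -
            e2(pops[2], pops[3])) / 2,
    f4 = (e2(pops[1], pops[4]) + e2(pops[2], pops[3]) -
            e2(pops[1], pops[3]) - e2(pops[2], pops[4])) / 2)
}
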