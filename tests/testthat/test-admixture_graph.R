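de3 <- function(p, c, v) data.frame(parent = p, child = c, type = "drift",
                                    value = v, free = TRUE)
am3 <- function(p, c, v) data.frame(parent = p, child = c, type = "admix",
                                    value = v, free = TRUE)

test_that("graph validation enforces the DAG invariants", {
  expect_error(admixture_graph(rbind(de3("a", "b", 1), de3("b", "a", 1))),
               "root")
  expect_error(admixture_graph(rbind(de3("r", "a", 1), de3("r", "b", 1),
                                     am3("a", "m", 0.6), am3("b", "m", 0.5),
                                     de3("m", "M", 1))),
               "sum to")
  expect_error(admixture_graph(de3("r", "a", -3)), "nonnegative")
  g <- fixture_graph("two_wave")
  expect_identical(g$root, "root")
  expect_true(all(c("L1", "L2", "O") %in% g$leaves))
})

test_that("graph files round-trip losslessly", {
  g <- fixture_graph("alpha_recovery")
  g$edges$value[3] <- 1 / 3          # non-terminating decimal
  g <- admixture_graph(g$edges)
  path <- withr::local_tempfile()
  write_graph(g, path)
  back <- read_graph(path)
  expect_identical(back$edges$parent, g$edges$parent)
  expect_identical(back$edges$value, g$edges$value)
  expect_identical(back$edges$free, g$edges$free)
})

test_that("leaf edge weights match exhaustive path enumeration", {
  # pure tree: 0/1 indicators of the root path
  tree <- admixture_graph(rbind(de3("r", "x", 1), de3("x", "A", 1),
                                de3("x", "B", 1), de3("r", "O", 1)))
  w <- leaf_edge_weights(tree)
  expect_identical(sort(unique(as.vector(w))), c(0, 1))
  expect_equal(w["A", "r->x"], 1)
  expect_equal(w["O", "r->x"], 0)
  # single admixture: alpha and 1 - alpha on the parent edges
  adm <- admixture_graph(rbind(de3("r", "u", 1), de3("r", "v", 1),
                               am3("u", "m", 0.3), am3("v", "m", 0.7),
                               de3("m", "M", 1)))
  wa <- leaf_edge_weights(adm)
  expect_equal(wa["M", "r->u"], 0.3)
  expect_equal(wa["M", "r->v"], 0.7)
  # nested admixture (0.3 then 0.5) discounts multiplicatively
  nested <- admixture_graph(rbind(
    de3("r", "u", 1), de3("r", "v", 1), de3("r", "t", 1),
    am3("u", "m1", 0.3), am3("v", "m1", 0.7), de3("m1", "x1", 1),
    am3("x1", "m2", 0.5), am3("t", "m2", 0.5), de3("m2", "M", 1),
    de3("u", "U", 1), de3("v", "V", 1), de3("t", "T", 1)))
  wn <- leaf_edge_weights(nested)
  expect_equal(wn["M", "r->u"], 0.15)
  expect_equal(wn["M", "r->v"], 0.35)
  expect_equal(wn["M", "r->t"], 0.5)
  # agreement with the brute-force path oracle on every fixture graph
  for (nm in c("single_wave", "two_wave", "three_source", "star_radiation",
               "anzick_affinity_toy", "alpha_recovery", "zero_edge")) {
    g <- fixture_graph(nm)
    got <- leaf_edge_weights(g)
    want <- oracle_leaf_weights(g)
    expect_equal(got, want[rownames(got), colnames(got)],
                 tolerance = 1e-12, label = nm)
  }
})

test_that("expected f-statistics follow the drift quadratic form", {
  g3 <- admixture_graph(rbind(de3("root", "X", 10), de3("X", "A", 5),
                              de3("X", "B", 7), de3("root", "O", 20)))
  expect_equal(expected_f2(g3, "A", "A"), 0)
  expect_equal(expected_f2(g3, "A", "B"), 12)
  expect_equal(expected_fstat(g3, "f3", c("O", "A", "B")), 30)
  # exact agreement with path enumeration on small and fixture graphs
  graphs <- list(g3,
                 admixture_graph(rbind(de3("r", "u", 4), de3("r", "v", 6),
                                       am3("u", "m", 0.25),
                                       am3("v", "m", 0.75),
                                       de3("m", "M", 3), de3("u", "U", 2),
                                       de3("v", "V", 8))),
                 fixture_graph("alpha_recovery"),
                 fixture_graph("zero_edge"))
  for (g in graphs) {
    lv <- g$leaves
    for (a in lv) for (b in lv)
      expect_equal(expected_f2(g, a, b), oracle_expected_f2(g, a, b),
                   tolerance = 1e-12)
  }
  # linearity: doubling every drift length doubles every expected f2
  gd <- g3; gd$edges$value <- gd$edges$value * 2
  gd <- admixture_graph(gd$edges)
  expect_equal(expected_f2(gd, "A", "B"), 2 * expected_f2(g3, "A", "B"))
  # model-side f4-from-f2 identity holds exactly
  g <- fixture_graph("alpha_recovery")
  f4 <- expected_fstat(g, "f4", c("A", "B", "C", "M"))
  expect_equal(f4, (expected_f2(g, "A", "M") + expected_f2(g, "B", "C") -
                      expected_f2(g, "A", "C") - expected_f2(g, "B", "M")) / 2,
               tolerance = 1e-12)
})

test_that("graph fitting recovers parameters and flags wrong topologies", {
  g <- fixture_graph("alpha_recovery")
  sim <- simulate_dataset(g, seed = 31, n_snps = 30000)
  ft <- allele_frequencies(sim$dataset)
  bl <- make_blocks(ft$snp, "count", n_blocks = 100)
  fit <- fit_graph(g, ft, bl, seed = 2, n_restarts = 4)
  expect_lt(fit$worst_z, 3.5)
  expect_lt(abs(fit$alpha[["mm"]] - 0.3), 0.1)
  expect_true(all(fit$drift >= 0))
  # residual table covers all f2 / f3 / f4 combinations of 6 leaves
  expect_identical(nrow(fit$residuals), 15L + 60L + 45L)
  # swapped-clade topology is strongly rejected
  fitw <- fit_graph(swap_leaves(g, "A", "C"), ft, bl, seed = 2,
                    n_restarts = 4)
  expect_gt(fitw$worst_z, 3.5)
  expect_error(fit_graph(g, random_freq_table(3, 50, 1), bl), "no data")
})

test_that("the extra-edge decision rule compares nested fits", {
  gtree <- fixture_graph("tree6")
  sim <- simulate_dataset(fixture_graph("alpha_recovery"), seed = 5,
                          n_snps = 30000)
  ft <- allele_frequencies(sim$dataset)
  bl <- make_blocks(ft$snp, "count", n_blocks = 100)
  cmp <- compare_with_edge(gtree, c("sd", "M"), c("pa", "A"), ft, bl,
                           alpha = 0.3, seed = 2, n_restarts = 3)
  expect_true(cmp$accept)
  expect_gt(cmp$delta_max_z, 0.3)
  # comparing a model against itself can never pass the rule
  simt <- simulate_dataset(gtree, seed = 6, n_snps = 20000)
  ftt <- allele_frequencies(simt$dataset)
  blt <- make_blocks(ftt$snp, "count", n_blocks = 100)
  base <- fit_graph(gtree, ftt, blt, seed = 2, n_restarts = 3)
  expect_false(base$worst_z - base$worst_z > 0.3)
})

test_that("graft search places candidates where they were generated", {
  skel <- admixture_graph(rbind(
    de3("root", "O", 60), de3("root", "x1", 15), de3("x1", "P", 30),
    de3("x1", "x2", 20), de3("x2", "Q", 30), de3("x2", "R", 30)))
  # clade case: S generated as sister of Q
  gen <- admixture_graph(rbind(
    de3("root", "O", 60), de3("root", "x1", 15), de3("x1", "P", 30),
    de3("x1", "x2", 20), de3("x2", "q0", 15), de3("q0", "Q", 15),
    de3("q0", "S", 15), de3("x2", "R", 30)))
  sim <- simulate_dataset(gen, seed = 41, n_snps = 20000)
  ft <- allele_frequencies(sim$dataset)
  bl <- make_blocks(ft$snp, "count", n_blocks = 100)
  res <- graft_search(skel, "S", ft, bl, seed = 2, n_restarts = 2)
  expect_gt(length(res$graphs), 0)
  placements <- vapply(res$graphs, function(s) s$history, "")
  expect_true(any(grepl("clade on x2->Q", placements)))
  # every returned graph actually fits
  for (s in res$graphs) expect_lte(s$fit$worst_z, 3.5)
  # empty candidate list returns the skeleton unchanged
  res0 <- graft_search(skel, character(0), ft, bl, seed = 2,
                       n_restarts = 2)
  expect_identical(length(res0$graphs), 1L)
  expect_identical(res0$graphs[[1]]$graph$edges, skel$edges)
})

test_that("graft search falls back to admixed placements for mixed candidates", {
  skel <- admixture_graph(rbind(
    de3("root", "O", 60), de3("root", "x1", 15), de3("x1", "P", 40),
    de3("x1", "x2", 25), de3("x2", "Q", 40), de3("x2", "R", 40)))
  gen <- admixture_graph(rbind(
    de3("root", "O", 60), de3("root", "x1", 15), de3("x1", "p0", 20),
    de3("p0", "P", 20), de3("x1", "x2", 25), de3("x2", "Q", 40),
    de3("x2", "r0", 20), de3("r0", "R", 20),
    am3("p0", "ms", 0.3), am3("r0", "ms", 0.7), de3("ms", "S", 10)))
  sim <- simulate_dataset(gen, seed = 43, n_snps = 30000)
  ft <- allele_frequencies(sim$dataset)
  bl <- make_blocks(ft$snp, "count", n_blocks = 100)
  res <- graft_search(skel, "S", ft, bl, seed = 2, n_restarts = 2)
  expect_gt(length(res$graphs), 0)
  hist <- vapply(res$graphs, function(s) s$history, "")
  expect_true(all(grepl("mixture", hist)))
  # some fitting placement mixes the P and R lineages with alpha near 0.3
  alphas <- vapply(res$graphs, function(s) {
    a <- s$fit$alpha
    if (length(a)) min(a, 1 - a) else NA_real_
  }, 0)
  expect_true(any(abs(alphas - 0.3) <= 0.07, na.rm = TRUE))
})

test_that("edge jackknife separates real from absent drift", {
  g <- fixture_graph("zero_edge")
  sim <- simulate_dataset(g, seed = 51, n_snps = 50000)
  ft <- allele_frequencies(sim$dataset)
  bl <- make_blocks(ft$snp, "count", n_blocks = 100)
  fit <- fit_graph(g, ft, bl, seed = 2, n_restarts = 4)
  ej <- edge_jackknife(fit, ft, n_blocks = 100)
  expect_identical(nrow(ej), sum(g$edges$type == "drift"))
  expect_true(all(ej$se >= 0))
  # strong true drift is significant; the z statistic scales the estimate
  expect_gt(ej$z_from_zero[ej$edge == "a0->A"], 3)
  expect_equal(ej$estimate, unname(fit$drift[ej$edge]), tolerance = 1e-9)
})
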