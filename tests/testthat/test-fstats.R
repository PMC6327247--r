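test_that("allele counting follows the per-ploidy call convention", {
  snp <- data.frame(snp_id = c("s1", "s2"), chrom = "1", genetic_pos = 0,
                    physical_pos = c(100L, 200L), allele1 = "A",
                    allele2 = "C")
  sample <- data.frame(sample_id = c("ph", "d1", "d2"), sex = "U",
                       group_label = c("anc", "mod", "mod"),
                       ploidy_mode = c("pseudo_haploid", "diploid",
                                       "diploid"))
  geno <- rbind(c(2L, NA), c(1L, 0L), c(1L, 2L))
  ft <- allele_frequencies(genotype_dataset(snp, sample, geno))
  expect_equal(ft$freq["anc", 1], 1)        # one call of allele1
  expect_equal(ft$count["anc", 1], 1)
  expect_equal(ft$count["anc", 2], 0)       # missing site
  expect_equal(ft$freq["mod", 1], 0.5)      # two hets: 2 of 4 calls
  expect_equal(ft$count["mod", 1], 4)
  # recount oracle on a simulated fixture
  fx <- make_fixture("two_wave", seed = 5, n_snps = 300)
  ft2 <- allele_frequencies(fx$dataset)
  pop <- "L2"
  idx <- fx$dataset$sample$group_label == pop
  ph <- fx$dataset$sample$ploidy_mode[idx] == "pseudo_haploid"
  for (s in c(1, 57, 300)) {
    gcol <- fx$dataset$geno[idx, s]
    a <- sum(ifelse(ph, gcol / 2, gcol), na.rm = TRUE)
    n <- sum(ifelse(ph, 1, 2)[!is.na(gcol)])
    expect_equal(unname(ft2$count[pop, s]), n + 0)
    if (n > 0) expect_equal(unname(ft2$freq[pop, s]), a / n)
  }
})

test_that("block building respects 5-Mb spans and equal-count mode", {
  snp <- data.frame(snp_id = paste0("s", 1:3), chrom = "1", genetic_pos = 0,
                    physical_pos = c(1L, 4999999L, 5000001L),
                    allele1 = "A", allele2 = "C")
  bl <- make_blocks(snp)
  expect_identical(bl$block_of, c(1L, 1L, 2L))
  snp10 <- data.frame(snp_id = paste0("s", 1:10), chrom = "1",
                      genetic_pos = 0, physical_pos = 1:10 * 10L,
                      allele1 = "A", allele2 = "C")
  bl5 <- make_blocks(snp10, "count", n_blocks = 5)
  expect_identical(bl5$weights, rep(2L, 5))
  expect_error(make_blocks(snp10[0, ]), "empty")
  # brute-force span check on a simulated 1240k-style map
  fx <- make_fixture("single_wave", seed = 8, n_snps = 20000)
  m <- fx$dataset$snp
  blk <- make_blocks(m)
  for (b in seq_len(blk$n_blocks)) {
    i <- which(blk$block_of == b)
    expect_identical(length(unique(m$chrom[i])), 1L)
    expect_lt(max(m$physical_pos[i]) - min(m$physical_pos[i]), 5e6)
  }
})

test_that("weighted block jackknife matches closed forms and loop oracle", {
  expect_equal(block_jackknife(c(5, 5, 5) * c(2, 3, 4) / 3,
                               c(2, 3, 4))$se, 0, tolerance = 1e-12)
  two <- block_jackknife(c(3, 7), c(1, 1))
  expect_equal(two$estimate, 5)
  expect_equal(two$se, 2)                    # |a - b| / 2
  set.seed(99)
  bs <- rnorm(50); bw <- sample(5:50, 50, replace = TRUE)
  got <- block_jackknife(bs, bw)
  want <- oracle_jackknife(bs, bw)
  expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
  expect_equal(got$se, want$se, tolerance = 1e-12)
  expect_equal(got$loo, want$loo, tolerance = 1e-12)
  expect_error(block_jackknife(c(1, 0), c(5, 0)), "2 blocks")
})

test_that("f-statistics satisfy exact identities", {
  ft <- random_freq_table(4, 400, seed = 31)
  bl <- make_blocks(ft$snp)
  # f4 with a repeated population is exactly zero
  expect_identical(f_statistic(ft, "f4", c("P1", "P1", "P2", "P3"),
                               bl)$estimate, 0)
  # corrected f2 of a population with itself is exactly zero
  expect_lt(abs(f_statistic(ft, "f2", c("P1", "P1"), bl)$estimate), 1e-12)
  # f4 from f2 identity on the same complete SNP set
  f2v <- function(a, b) f_statistic(ft, "f2", c(a, b), bl)$estimate
  f4 <- f_statistic(ft, "f4", c("P1", "P2", "P3", "P4"), bl)$estimate
  expect_equal(f4, (f2v("P1", "P4") + f2v("P2", "P3") -
                      f2v("P1", "P3") - f2v("P2", "P4")) / 2,
               tolerance = 1e-10)
  # exact-frequency example: p_A = (1,0), p_B = (0,0), p_X = (1,0),
  # p_Y = (0,0) with infinite counts gives f4 = 0.5
  snp2 <- ft$snp[1:2, ]
  ft2 <- freq_table(c("A", "B", "X", "Y"),
                    rbind(c(1, 0), c(0, 0), c(1, 0), c(0, 0)),
                    matrix(Inf, 4, 2), snp2)
  bl2 <- make_blocks(snp2, "count", n_blocks = 2)
  expect_equal(f_statistic(ft2, "f4", c("A", "B", "X", "Y"), bl2)$estimate,
               0.5)
  # z * se = estimate; block bookkeeping is consistent
  est <- f_statistic(ft, "f3", c("P1", "P2", "P3"), bl)
  expect_equal(est$z * est$se, est$estimate)
  expect_gte(est$n_blocks_used, 2)
})

test_that("every statistic matches the naive direct-summation oracle", {
  ft <- random_freq_table(5, 200, seed = 77)
  bl <- make_blocks(ft$snp, "count", n_blocks = 8)
  cases <- list(list("f2", c("P1", "P2")),
                list("f3", c("P3", "P1", "P2")),
                list("f4", c("P1", "P2", "P3", "P4")),
                list("D", c("P1", "P2", "P3", "P4")))
  for (cs in cases) {
    for (inb in c(TRUE, FALSE)) {
      got <- f_statistic(ft, cs[[1]], cs[[2]], bl, inbreed = inb)$estimate
      want <- oracle_fstat(ft, cs[[1]], cs[[2]], inbreed = inb)
      expect_equal(got, want, tolerance = 1e-12,
                   label = paste(cs[[1]], inb))
    }
  }
})

test_that("missing data routes through per-statistic SNP intersection", {
  ft <- random_freq_table(3, 60, seed = 5)
  ft$count["P3", 1:20] <- 0
  bl <- make_blocks(ft$snp, "count", n_blocks = 4)
  a <- f_statistic(ft, "f2", c("P1", "P2"), bl)
  expect_identical(a$n_snps_used, 60L)
  b <- f_statistic(ft, "f3", c("P3", "P1", "P2"), bl)
  expect_identical(b$n_snps_used, 40L)
  g <- f_statistic(ft, "f2", c("P1", "P2"), bl, snp_set = "global")
  expect_identical(g$n_snps_used, 40L)
})

test_that("outgroup-f3 matrices are symmetric and track shared drift", {
  fx <- make_fixture("single_wave", seed = 13, n_snps = 40000)
  ft <- fx$freq_table                       # exact frequencies
  bl <- make_blocks(ft$snp)
  pops <- c("L1", "R3", "R5")
  m <- outgroup_f3_matrix(ft, "O", pops, bl)
  expect_identical(m$values, t(m$values))
  # drift-attenuated graph expectation in raw frequency units
  g <- fx$truth$graph
  for (i in 1:3) for (j in 1:3) {
    want <- oracle_raw_expectation(g, "f3", c("O", pops[i], pops[j]))
    se <- max(m$ses[i, j], 1e-12, na.rm = TRUE)
    expect_lt(abs(m$values[i, j] - want), 3 * se + 1e-9)
  }
  # caterpillar monotonicity: populations splitting later share more
  # drift with the deepest leaf
  chain <- outgroup_f3_matrix(ft, "O", c("L1", "R1", "R3", "R5"), bl)
  expect_lt(chain$values["L1", "R1"], chain$values["L1", "R3"])
  expect_lt(chain$values["L1", "R3"], chain$values["L1", "R5"])
})

test_that("f4 scans rank admixed leaves above unadmixed ones", {
  fx <- make_fixture("anzick_affinity_toy", seed = 19, n_snps = 30000)
  ft <- allele_frequencies(fx$dataset)
  bl <- make_blocks(ft$snp)
  tab <- scan_f4(ft, c("O", NA, "U", "ANZ"),
                 c("L1", "L2", "L3", "L4", "L5"), bl)
  expect_identical(nrow(tab), 5L)
  # the two leaves carrying the extra lineage rank on top
  expect_setequal(tab$test[1:2], c("L4", "L5"))
  # a test population duplicating the fixed slot of its pair gives zero
  tab0 <- scan_f4(ft, c("O", NA, "U", "ANZ"), "O", bl)
  expect_identical(tab0$estimate, 0)
  expect_error(scan_f4(ft, c("O", NA, "U", "ANZ"), character(0), bl),
               "empty")
})
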