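# f2 / f3 / f4 / D statistics from per-population allele frequencies, with
# weighted block-jackknife standard errors.
#
# Per-SNP summands:
#   f4(A,B; X,Y): (pA - pB)(pX - pY)
#   f2(A,B):      (pA - pB)^2  - hA/nA - hB/nB          (corrected)
#   f3(C; A,B):   (pC - pA)(pC - pB) - hC/nC            (corrected)
#   D(A,B; X,Y):  sum (pA-pB)(pX-pY) / sum (pA+pB-2 pA pB)(pX+pY-2 pX pY)
# where h/n = p(1-p)/(n-1) is the finite-sample bias term built from the
# unbiased estimate of p(1-p); with allele counts tallied one per
# pseudo-haploid call this estimates heterozygosity from between-individual
# mismatches, which is the correction required when individuals are
# represented by a single random allele ("inbreed" mode).  Setting
# `inbreed = FALSE` disables the subtraction, reproducing the upward-biased
# naive estimator for contrast checks.

#' Construct a per-population frequency table
#'
#' @param pops ordered population labels.
#' @param freq numeric matrix (populations x SNPs) of allele1 frequencies.
#' @param count matrix of observed allele-call counts (0 marks the site
#'   missing for that population; `Inf` denotes exact population
#'   frequencies, as produced by the simulator).
#' @param snp the SNP map (same columns as in a [genotype_dataset()]).
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(pops, freq, count, snp) {
  freq <- as.matrix(freq); count <- as.matrix(count)
  rownames(freq) <- rownames(count) <- pops
  ok <- count > 0
  if (any(freq[ok] < -1e-12 | freq[ok] > 1 + 1e-12, na.rm = TRUE))
    stopf("frequencies outside [0, 1]")
  if (any(count < 0)) stopf("counts must be nonnegative")
  structure(list(pops = pops, freq = freq, count = count,
                 snp = as.data.frame(snp)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d populations x %d SNPs\n", length(x$pops),
              ncol(x$freq)))
  invisible(x)
}

#' Per-group allele frequencies and call counts
#'
#' Tallies observed allele calls per (group, SNP): each non-missing diploid
#' genotype contributes two calls, each pseudo-haploid genotype one call
#' (its 0/2 code representing a single randomly drawn allele).  A count of
#' zero marks the site unusable for that group.
#'
#' @param dataset a [genotype_dataset()].
#' @param groups optional character vector (one label per sample)
#'   overriding the dataset's `group_label`s.
#' @return A [freq_table()].
#' @export
allele_frequencies <- function(dataset, groups = NULL) {
  groups <- groups %||% dataset$sample$group_label
  if (length(groups) != nrow(dataset$sample))
    stopf("groups must have one label per sample")
  g <- dataset$geno
  ph <- dataset$sample$ploidy_mode == "pseudo_haploid"
  acalls <- g; acalls[ph, ] <- acalls[ph, , drop = FALSE] / 2L
  ncalls <- (!is.na(g)) * ifelse(ph, 1L, 2L)
  acalls[is.na(acalls)] <- 0
  pops <- unique(groups)
  fac <- factor(groups, levels = pops)
  A <- rowsum(acalls, fac)
  N <- rowsum(ncalls, fac)
  f <- A / N
  f[N == 0] <- NA_real_
  freq_table(pops, f, N, dataset$snp)
}

#' Partition SNPs into jackknife blocks
#'
#' In `"span"` mode blocks are greedy left-to-right runs of SNPs covering
#' at most `span` bp of physical position (half-open windows anchored at
#' the first SNP of each block), never crossing a chromosome boundary.  In
#' `"count"` mode the SNPs are split into exactly `n_blocks` contiguous
#' runs of equal size (+/- 1), ignoring chromosomes.
#'
#' @param snp a SNP map (position-sorted within chromosome).
#' @param mode `"span"` (default, 5-Mb genomic blocks) or `"count"`.
#' @param span block span in bp for `"span"` mode.
#' @param n_blocks number of blocks for `"count"` mode.
#' @return An object of class `block_partition` with fields `block_of`
#'   (block id per SNP), `n_blocks` and `weights` (SNPs per block).
#' @export
make_blocks <- function(snp, mode = c("span", "count"), span = 5e6,
                        n_blocks = 100) {
  mode <- match.arg(mode)
  n <- nrow(snp)
  if (n == 0) stopf("empty SNP table")
  if (mode == "span") {
    ids <- integer(n)
    bid <- 0L
    for (ch in unique(snp$chrom)) {
      idx <- which(snp$chrom == ch)
      pos <- snp$physical_pos[idx]
      start <- -Inf
      for (i in seq_along(idx)) {
        if (pos[i] >= start + span) { bid <- bid + 1L; start <- pos[i] }
        ids[idx[i]] <- bid
      }
    }
  } else {
    if (n_blocks < 1 || n_blocks > n)
      stopf("n_blocks must be between 1 and the number of SNPs")
    ids <- as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
  }
  structure(list(block_of = ids, n_blocks = max(ids),
                 weights = tabulate(ids, nbins = max(ids))),
            class = "block_partition")
}

#' Weighted block jackknife from per-block sums
#'
#' Given per-block sums of a statistic's per-SNP summands and per-block
#' usable-SNP counts, returns the overall estimate (ratio of total sum to
#' total weight), the weighted delete-one-block jackknife standard error
#' (Busing's formula for unequal block sizes), and the leave-one-out
#' estimates.
#'
#' @param block_sums numeric vector of per-block summand sums.
#' @param block_weights per-block usable-SNP counts.
#' @return A list with `estimate`, `se`, `loo` and `n_blocks_used` (blocks
#'   with nonzero weight).
#' @export
block_jackknife <- function(block_sums, block_weights) {
  tot <- sum(block_sums); n <- sum(block_weights)
  if (n <= 0) stopf("zero total weight")
  est <- tot / n
  loo <- ifelse(block_weights < n,
                (tot - block_sums) / (n - block_weights), est)
  loo[block_weights == 0] <- est
  res <- jackknife_from_loo(est, loo, block_weights)
  c(list(estimate = est), res)
}

# Weighted jackknife variance from an estimate, its leave-one-out values
# and block weights.  Blocks with zero weight contribute nothing.
jackknife_from_loo <- function(est, loo, w) {
  use <- w > 0
  g <- sum(use)
  if (g < 2) stopf("jackknife needs at least 2 blocks with nonzero weight")
  n <- sum(w)
  h <- n / w[use]
  tau <- h * est - (h - 1) * loo[use]
  theta_j <- g * est - sum((1 - w[use] / n) * loo[use])
  var <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(se = sqrt(var), loo = loo, n_blocks_used = g)
}

# ---- summand machinery ------------------------------------------------

fstat_arity <- c(f2 = 2L, f3 = 3L, f4 = 4L, D = 4L)

# Frequency / count rows for the named populations, with errors on
# unknown labels.
ft_rows <- function(ft, pops) {
  bad <- setdiff(pops, ft$pops)
  if (length(bad)) stopf("unknown population(s): %s", paste(bad, collapse = ", "))
  list(p = ft$freq[pops, , drop = FALSE], n = ft$count[pops, , drop = FALSE])
}

# h/n bias term: p(1-p)/(n-1); 0 for exact (infinite-count) frequencies.
bias_term <- function(p, n) {
  out <- p * (1 - p) / (n - 1)
  out[!is.finite(n)] <- 0
  out
}

# Per-SNP summands and usability mask for one statistic.
fstat_summands <- function(ft, kind, pops, inbreed = TRUE,
                           snp_set = "per_statistic") {
  if (!kind %in% names(fstat_arity)) stopf("unknown statistic kind: %s", kind)
  if (length(pops) != fstat_arity[[kind]])
    stopf("%s takes %d populations, got %d", kind, fstat_arity[[kind]],
          length(pops))
  r <- ft_rows(ft, pops)
  p <- r$p; n <- r$n
  usable <- colSums(n > 0) == nrow(n)
  if (snp_set == "global") usable <- usable & colSums(ft$count > 0) == length(ft$pops)
  den <- NULL
  if (kind == "f2") {
    # identical arguments name the same samples: the statistic is exactly
    # zero and the disjoint-sample bias terms do not apply
    if (pops[1] == pops[2])
      return(list(num = numeric(ncol(p)), den = NULL, usable = usable))
    num <- (p[1, ] - p[2, ])^2
    if (inbreed) {
      num <- num - bias_term(p[1, ], n[1, ]) - bias_term(p[2, ], n[2, ])
      usable <- usable & (n[1, ] >= 2 | !is.finite(n[1, ])) &
        (n[2, ] >= 2 | !is.finite(n[2, ]))
    }
  } else if (kind == "f3") {
    num <- (p[1, ] - p[2, ]) * (p[1, ] - p[3, ])
    if (inbreed) {
      num <- num - bias_term(p[1, ], n[1, ])
      usable <- usable & (n[1, ] >= 2 | !is.finite(n[1, ]))
    }
  } else {
    num <- (p[1, ] - p[2, ]) * (p[3, ] - p[4, ])
    if (kind == "D")
      den <- (p[1, ] + p[2, ] - 2 * p[1, ] * p[2, ]) *
        (p[3, ] + p[4, ] - 2 * p[3, ] * p[4, ])
  }
  num[!usable] <- 0
  if (!is.null(den)) den[!usable] <- 0
  list(num = num, den = den, usable = usable)
}

block_sums <- function(x, blocks) {
  out <- numeric(blocks$n_blocks)
  s <- rowsum(x, blocks$block_of)
  out[as.integer(rownames(s))] <- s
  out
}

#' Estimate an f-statistic or D-statistic with jackknife errors
#'
#' @param ft a [freq_table()].
#' @param kind `"f2"`, `"f3"`, `"f4"` or `"D"`.
#' @param pops population labels: `c(A, B)` for f2, `c(C, A, B)` for
#'   f3(C; A, B), `c(A, B, X, Y)` for f4/D.
#' @param blocks a [make_blocks()] partition of the table's SNPs.
#' @param inbreed logical; apply the finite-sample heterozygosity
#'   correction to f2/f3 (see the module notes above).  Required when
#'   populations are represented by single random alleles per site.
#' @param snp_set `"per_statistic"` (default: a SNP is used whenever every
#'   population named in this statistic has data there) or `"global"`
#'   (restrict to SNPs present in every population of the table).
#' @return An object of class `fstat_estimate` with fields `kind`, `pops`,
#'   `estimate`, `se`, `z`, `n_snps_used`, `n_blocks_used`,
#'   `per_block_loo`.
#' @export
f_statistic <- function(ft, kind, pops, blocks, inbreed = TRUE,
                        snp_set = c("per_statistic", "global")) {
  snp_set <- match.arg(snp_set)
  s <- fstat_summands(ft, kind, pops, inbreed, snp_set)
  if (!any(s$usable)) stopf("no usable SNPs for %s(%s)", kind,
                            paste(pops, collapse = ", "))
  w <- block_sums(as.numeric(s$usable), blocks)
  if (sum(w > 0) < 2)
    stopf("fewer than 2 jackknife blocks with data; SE undefined")
  if (kind == "D") {
    bn <- block_sums(s$num, blocks); bd <- block_sums(s$den, blocks)
    tn <- sum(bn); td <- sum(bd)
    if (td == 0) stopf("zero D-statistic denominator")
    est <- tn / td
    loo <- ifelse(bd < td, (tn - bn) / (td - bd), est)
    loo[w == 0] <- est
    jk <- jackknife_from_loo(est, loo, w)
  } else {
    bs <- block_sums(s$num, blocks)
    jk <- block_jackknife(bs, w)
    est <- jk$estimate
  }
  structure(list(kind = kind, pops = pops, estimate = est, se = jk$se,
                 z = est / jk$se, n_snps_used = sum(s$usable),
                 n_blocks_used = jk$n_blocks_used, per_block_loo = jk$loo),
            class = "fstat_estimate")
}

#' @export
print.fstat_estimate <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.2f  (%d SNPs, %d blocks)\n",
              x$kind, paste(x$pops, collapse = ", "), x$estimate, x$se,
              x$z, x$n_snps_used, x$n_blocks_used))
  invisible(x)
}

# Joint computation of several (non-D) statistics: estimates, SEs,
# leave-one-out matrices and (optionally) the jackknife covariance of the
# vector of estimates.  The covariance generalizes Busing's weighted
# formula: entry deviations are scaled by 1/sqrt(h_j - 1) per statistic,
# cross-moments normalized by sqrt(g_i g_k), so the diagonal equals the
# per-statistic jackknife variances exactly.
fstat_block_table <- function(ft, stats, blocks, inbreed = TRUE,
                              want_cov = FALSE, snp_set = "per_statistic") {
  d <- length(stats)
  g <- blocks$n_blocks
  BS <- matrix(0, g, d); W <- matrix(0, g, d)
  n_snps <- integer(d)
  for (i in seq_len(d)) {
    s <- fstat_summands(ft, stats[[i]]$kind, stats[[i]]$pops, inbreed,
                        snp_set)
    BS[, i] <- block_sums(s$num, blocks)
    W[, i] <- block_sums(as.numeric(s$usable), blocks)
    n_snps[i] <- sum(s$usable)
  }
  if (any(n_snps == 0)) {
    bad <- which(n_snps == 0)[1]
    stopf("no usable SNPs for %s(%s)", stats[[bad]]$kind,
          paste(stats[[bad]]$pops, collapse = ", "))
  }
  tot <- colSums(BS); n <- colSums(W)
  est <- tot / n
  denom <- sweep(-W, 2, n, "+")           # n_i - w_ji
  loo <- sweep(-BS, 2, tot, "+") / denom
  loo[W == 0] <- rep(est, each = g)[W == 0]
  use <- W > 0
  gi <- colSums(use)
  if (any(gi < 2)) stopf("fewer than 2 jackknife blocks with data")
  H <- sweep(1 / W, 2, n, "*")            # h_ji = n_i / w_ji
  TAU <- sweep(-sweep(loo, 2, est, "-") * (H - 1), 2, est, "+")
  TAU[!use] <- rep(est, each = g)[!use]
  theta_j <- gi * est - colSums((1 - sweep(W, 2, n, "/")) * loo * use)
  DEV <- sweep(TAU, 2, theta_j, "-") / sqrt(H - 1)
  DEV[!use] <- 0
  var <- colSums(DEV^2) / gi
  out <- list(stats = stats, estimate = est, se = sqrt(var),
              z = est / sqrt(var), loo = loo, weights = W,
              n_snps = n_snps, n_blocks_used = gi)
  if (want_cov)
    out$cov <- crossprod(DEV) / outer(sqrt(gi), sqrt(gi))
  out
}

#' Outgroup-f3 shared-drift matrix
#'
#' Computes `f3(outgroup; i, j)` for all pairs of populations; the value
#' measures the genetic drift shared by `i` and `j` after they diverged
#' from the outgroup.  The matrix is symmetric with `f3(outgroup; i, i)`
#' on the diagonal; cells whose statistic cannot be computed are recorded
#' as `NA`.
#'
#' @inheritParams f_statistic
#' @param outgroup outgroup population label.
#' @param pops populations to compare (at least 2).
#' @return An object of class `f3_matrix` with fields `outgroup`, `pops`,
#'   `values`, `ses`.
#' @export
outgroup_f3_matrix <- function(ft, outgroup, pops, blocks, inbreed = TRUE) {
  if (length(pops) < 2) stopf("need at least 2 populations")
  k <- length(pops)
  V <- SE <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) for (j in i:k) {
    cell <- tryCatch(
      f_statistic(ft, "f3", c(outgroup, pops[i], pops[j]), blocks, inbreed),
      error = function(e) NULL)
    if (!is.null(cell)) {
      V[i, j] <- V[j, i] <- cell$estimate
      SE[i, j] <- SE[j, i] <- cell$se
    }
  }
  structure(list(outgroup = outgroup, pops = pops, values = V, ses = SE),
            class = "f3_matrix")
}

#' @export
print.f3_matrix <- function(x, ...) {
  cat(sprintf("outgroup-f3 matrix (outgroup %s, %d populations)\n",
              x$outgroup, length(x$pops)))
  print(round(x$values, 5))
  invisible(x)
}

#' Scan an f4 template over test populations
#'
#' Evaluates an f4 statistic with one free slot for each test population,
#' e.g. `f4(Outgroup, Test; Anchor1, Anchor2)` to measure how much each
#' test population shares alleles with one anchor over the other.
#'
#' @inheritParams f_statistic
#' @param template character vector of length 4 with exactly one `NA`
#'   marking the free slot.
#' @param test_pops populations to substitute into the free slot.
#' @return A data frame, one row per test population, with the estimate,
#'   SE, Z and SNP/block counts, sorted by decreasing Z.
#' @export
scan_f4 <- function(ft, template, test_pops, blocks, inbreed = TRUE) {
  if (length(template) != 4 || sum(is.na(template)) != 1)
    stopf("template must have length 4 with exactly one free (NA) slot")
  if (!length(test_pops)) stopf("empty test population set")
  slot <- which(is.na(template))
  rows <- lapply(test_pops, function(tp) {
    pops <- template; pops[slot] <- tp
    est <- tryCatch(f_statistic(ft, "f4", pops, blocks, inbreed),
                    error = function(e) NULL)
    if (is.null(est))
      data.frame(test = tp, estimate = NA_real_, se = NA_real_,
                 z = NA_real_, n_snps = NA_integer_, n_blocks = NA_integer_)
    else
      data.frame(test = tp, estimate = est$estimate, se = est$se,
                 z = est$z, n_snps = est$n_snps_used,
                 n_blocks = est$n_blocks_used)
  })
  out <- do.call(rbind, rows)
  out[order(-out$z), , drop = FALSE]
}
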