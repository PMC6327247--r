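# Rank test for the minimum number of ancestry streams relating a set of
# "left" (test) populations to a set of "right" outgroups.
#
# The matrix E of f4(left_0, left_i; right_0, right_j) statistics has rank
# at most k when the left populations derive from k + 1 streams of
# ancestry relative to the rights.  Rank k is tested by fitting the best
# rank-k approximation under the jackknife covariance of the entries and
# referring the residual quadratic form to a chi-square distribution with
# (L - 1 - k)(R - 1 - k) degrees of freedom; a Hotelling-style
# small-sample correction to an F reference is available as an option.

#' Matrix of f4 statistics with joint jackknife covariance
#'
#' @param ft a [freq_table()].
#' @param left test population labels (L >= 2); the first is the basis.
#' @param right outgroup labels (R >= 2); the first is the basis.
#' @param blocks a [make_blocks()] partition.
#' @return An object of class `f4_matrix` with the (L-1) x (R-1) matrix
#'   `E`, the jackknife covariance `cov` of `vec(E)` (column-major), the
#'   per-entry standard errors `se`, and block bookkeeping.
#' @export
build_f4_matrix <- function(ft, left, right, blocks) {
  if (length(left) < 2 || length(right) < 2)
    stopf("need at least 2 left and 2 right populations")
  stats <- list()
  for (j in right[-1]) for (i in left[-1])
    stats[[length(stats) + 1L]] <- list(kind = "f4",
                                        pops = c(left[1], i, right[1], j))
  tab <- fstat_block_table(ft, stats, blocks, inbreed = FALSE,
                           want_cov = TRUE)
  L1 <- length(left) - 1L; R1 <- length(right) - 1L
  E <- matrix(tab$estimate, L1, R1,
              dimnames = list(left[-1], right[-1]))
  structure(list(left = left, right = right, E = E, cov = tab$cov,
                 se = matrix(tab$se, L1, R1),
                 n_blocks = min(tab$n_blocks_used),
                 n_snps = tab$n_snps),
            class = "f4_matrix")
}

#' @export
print.f4_matrix <- function(x, ...) {
  cat(sprintf("f4_matrix: %d x %d (lefts: %s | rights: %s)\n", nrow(x$E),
              ncol(x$E), paste(x$left, collapse = ","),
              paste(x$right, collapse = ",")))
  invisible(x)
}

# Inverse covariance with documented ridge regularization when the
# jackknife covariance is (near-)singular.
regularized_inverse <- function(C, ridge = 1e-6) {
  ridged <- FALSE
  Ci <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(Ci) || !all(is.finite(Ci)) || rcond(C) < 1e-12) {
    eps <- ridge * mean(diag(C))
    if (!is.finite(eps) || eps <= 0) eps <- ridge
    C <- C + diag(eps, nrow(C))
    Ci <- chol2inv(chol(C))
    ridged <- TRUE
  }
  list(inv = Ci, ridged = ridged)
}

#' Test the rank of an f4 matrix
#'
#' Fits the best rank-`k` approximation `E ~ A B'` by covariance-weighted
#' alternating generalized least squares and evaluates the residual
#' quadratic form.  `k = 0` tests a single stream of ancestry, `k = 1` two
#' streams, and so on; `k` must be below `min(L-1, R-1)` for the test to
#' have positive degrees of freedom.
#'
#' @param f4_matrix an object from [build_f4_matrix()].
#' @param k rank to test.
#' @param method `"chisq"` (default) refers the statistic to a chi-square
#'   with `(L-1-k)(R-1-k)` dof; `"hotelling"` applies the small-sample
#'   correction `(g - d) / (d (g - 1)) T^2 ~ F(d, g - d)` with `g` the
#'   number of jackknife blocks.
#' @param weighting `"full"` uses the full jackknife covariance of the
#'   entries; `"diagonal"` keeps only the per-entry variances.
#' @param ridge relative ridge added to a singular covariance (flagged in
#'   the result).
#' @param tol,max_iter convergence controls for the alternating fit.
#' @return An object of class `rank_test_result` with fields `k`,
#'   `statistic`, `dof`, `p_value`, `converged`, `ridged`.
#' @export
test_rank <- function(f4_matrix, k, method = c("chisq", "hotelling"),
                      weighting = c("full", "diagonal"), ridge = 1e-6,
                      tol = 1e-8, max_iter = 10000) {
  method <- match.arg(method); weighting <- match.arg(weighting)
  E <- f4_matrix$E
  L1 <- nrow(E); R1 <- ncol(E)
  if (k < 0 || k >= min(L1, R1))
    stopf("rank %d is untestable for a %d x %d matrix (dof would be <= 0)",
          k, L1, R1)
  C <- f4_matrix$cov
  if (weighting == "diagonal") C <- diag(diag(C), nrow(C))
  ri <- regularized_inverse(C, ridge)
  Ci <- ri$inv
  y <- as.vector(E)
  converged <- TRUE
  if (k == 0) {
    stat <- drop(t(y) %*% Ci %*% y)
  } else {
    sv <- svd(E)
    A <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], k)
    B <- sv$v[, seq_len(k), drop = FALSE]
    obj <- Inf
    IL <- diag(L1); IR <- diag(R1)
    for (it in seq_len(max_iter)) {
      # solve for A given B:  vec(A B') = (B (x) I_L1) vec(A)
      X <- kronecker(B, IL)
      M <- crossprod(X, Ci)
      A <- matrix(solve(M %*% X, M %*% y), L1, k)
      # solve for B given A:  vec(A B') = (I_R1 (x) A) vec(B')
      X <- kronecker(IR, A)
      M <- crossprod(X, Ci)
      B <- t(matrix(solve(M %*% X, M %*% y), k, R1))
      r <- y - as.vector(A %*% t(B))
      new_obj <- drop(t(r) %*% Ci %*% r)
      if (is.finite(obj) && abs(obj - new_obj) < tol * max(1, abs(new_obj))) {
        obj <- new_obj; break
      }
      obj <- new_obj
      if (it == max_iter) converged <- FALSE
    }
    stat <- obj
  }
  dof <- (L1 - k) * (R1 - k)
  g <- f4_matrix$n_blocks
  p <- if (method == "chisq") {
    pchisq(stat, dof, lower.tail = FALSE)
  } else {
    if (g <= dof) stopf("Hotelling correction needs more blocks than dof")
    pf(stat * (g - dof) / (dof * (g - 1)), dof, g - dof, lower.tail = FALSE)
  }
  structure(list(k = k, statistic = stat, dof = dof, p_value = p,
                 converged = converged, ridged = ri$ridged),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("rank %d: statistic %.3f, dof %d, p = %.4g%s%s\n", x$k,
              x$statistic, x$dof, x$p_value,
              if (!x$converged) " (not converged)" else "",
              if (x$ridged) " (ridged covariance)" else ""))
  invisible(x)
}

#' Scan candidate population sets for their minimum number of streams
#'
#' For every candidate set of test populations, tests ranks 0 up to
#' `size - 2` against a fixed outgroup set and reports the smallest
#' non-rejected rank plus one as the number of ancestry streams consistent
#' with the data (`size` if every testable rank is rejected).
#' Outgroup-sensitivity reruns are performed by passing a reduced `right`.
#'
#' @param ft a [freq_table()].
#' @param candidate_sets list of character vectors of test populations.
#' @param right outgroup labels, fixed across the scan.
#' @param blocks a [make_blocks()] partition.
#' @param alpha rejection threshold for the per-rank p-values.
#' @param ... passed to [test_rank()].
#' @return A data frame with one row per candidate set: the set, its size,
#'   the p-value for each tested rank (columns `p_rank0`, `p_rank1`, ...)
#'   and `n_streams`.  Sets whose populations are absent from the data get
#'   an `error` message and NA results; the scan continues.
#' @export
wave_scan <- function(ft, candidate_sets, right, blocks, alpha = 0.01, ...) {
  if (!length(candidate_sets)) stopf("empty candidate set list")
  max_rank <- max(lengths(candidate_sets)) - 2L
  rows <- lapply(candidate_sets, function(set) {
    out <- data.frame(set = paste(set, collapse = "+"),
                      size = length(set), stringsAsFactors = FALSE)
    for (k in 0:max(0L, max_rank)) out[[paste0("p_rank", k)]] <- NA_real_
    out$n_streams <- NA_integer_; out$error <- NA_character_
    res <- tryCatch({
      fm <- build_f4_matrix(ft, set, right, blocks)
      ks <- seq.int(0L, length(set) - 2L)
      ps <- vapply(ks, function(k) test_rank(fm, k, ...)$p_value, 0)
      list(ks = ks, ps = ps)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$error <- res
    } else {
      for (i in seq_along(res$ks))
        out[[paste0("p_rank", res$ks[i])]] <- res$ps[i]
      accepted <- which(res$ps >= alpha)
      out$n_streams <- if (length(accepted)) res$ks[accepted[1]] + 1L
                       else length(set)
    }
    out
  })
  do.call(rbind, rows)
}
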