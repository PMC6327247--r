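# Fitting admixture graphs to observed f-statistics.
#
# The fit basis is the set of all leaf-pair f2 statistics with their full
# jackknife covariance.  Observed statistics are converted to the graph's
# F_ST x 1000 units by dividing by lambda-hat, the mean unbiased estimate
# of p(1-p) across leaf populations (a heterozygosity normalizer, so the
# fitted edge lengths are comparable to drift units); residual Z-scores
# are invariant to this scaling.  For fixed admixture proportions the
# expected f2 vector is linear in the drift lengths, which are solved by
# nonnegativity-constrained GLS (whitened nonnegative least squares);
# the proportions are optimized by bounded quasi-Newton search with
# seeded random multi-starts.  The residual report enumerates all f2, f3
# and f4 combinations of the leaves, with expected values derived from
# the fitted f2 parameterization (so the model side satisfies the
# f4-from-f2 identity exactly), and the fit quality is summarized by the
# worst |Z| between observed and expected statistics.

# Nonnegative least squares robust to structural rank deficiency: some
# edge combinations (e.g. the two branches meeting at the root) are only
# jointly identifiable from f2 statistics, so an infinitesimal Tikhonov
# term is added to make the solution unique; identifiable edges are
# unaffected at this magnitude.
nnls_solve <- function(M, y) {
  p <- ncol(M)
  tau <- sqrt(1e-10 * max(colSums(M^2), 1e-300))
  sol <- pracma::lsqnonneg(rbind(M, diag(tau, p)), c(y, numeric(p)))
  list(x = sol$x, obj = sum((y - M %*% sol$x)^2))
}

# All f2 pairs / f3 triples / f4 quadruple-pairings of a leaf set.
enumerate_basis <- function(leaves) {
  pairs <- combn(leaves, 2, simplify = FALSE)
  lapply(pairs, function(p) list(kind = "f2", pops = p))
}

enumerate_residual_stats <- function(leaves) {
  out <- enumerate_basis(leaves)
  for (cpop in leaves) {
    others <- setdiff(leaves, cpop)
    for (p in combn(others, 2, simplify = FALSE))
      out[[length(out) + 1L]] <- list(kind = "f3", pops = c(cpop, p))
  }
  if (length(leaves) >= 4) {
    for (q in combn(leaves, 4, simplify = FALSE)) {
      out[[length(out) + 1L]] <- list(kind = "f4", pops = q)
      out[[length(out) + 1L]] <- list(kind = "f4", pops = q[c(1, 3, 2, 4)])
      out[[length(out) + 1L]] <- list(kind = "f4", pops = q[c(1, 4, 2, 3)])
    }
  }
  out
}

# Heterozygosity normalizer: mean unbiased p(1-p) over leaf populations.
het_normalizer <- function(ft, leaves) {
  p <- ft$freq[leaves, , drop = FALSE]
  n <- ft$count[leaves, , drop = FALSE]
  h <- p * (1 - p) * n / (n - 1)
  h[!is.finite(n)] <- (p * (1 - p))[!is.finite(n)]
  ok <- (n >= 2) | !is.finite(n)
  mean(h[ok], na.rm = TRUE)
}

# Expected statistic from a weight matrix and drift-length vector.
exp_from_w <- function(w, ce, kind, pops) {
  e2 <- function(a, b) sum((w[a, ] - w[b, ])^2 * ce)
  switch(kind,
    f2 = e2(pops[1], pops[2]),
    f3 = (e2(pops[1], pops[2]) + e2(pops[1], pops[3]) -
            e2(pops[2], pops[3])) / 2,
    f4 = (e2(pops[1], pops[4]) + e2(pops[2], pops[3]) -
            e2(pops[1], pops[3]) - e2(pops[2], pops[4])) / 2)
}

# Free admixture proportions of a graph: one parameter per admixture
# node, attached to its first-listed admix edge.
alpha_params <- function(graph) {
  e <- graph$edges
  nodes <- unique(e$child[e$type == "admix"])
  if (!length(nodes)) return(data.frame(node = character(0),
                                        i1 = integer(0), i2 = integer(0),
                                        value = numeric(0), free = logical(0)))
  rows <- lapply(nodes, function(v) {
    idx <- which(e$type == "admix" & e$child == v)
    data.frame(node = v, i1 = idx[1], i2 = idx[2], value = e$value[idx[1]],
               free = e$free[idx[1]] && e$free[idx[2]])
  })
  do.call(rbind, rows)
}

set_alphas <- function(graph, ap, values) {
  e <- graph$edges
  e$value[ap$i1] <- values
  e$value[ap$i2] <- 1 - values
  graph$edges <- e
  graph
}

#' Fit an admixture graph to observed f-statistics
#'
#' @param graph an [admixture_graph()] giving the topology; drift lengths
#'   and admixture proportions flagged `free` are re-estimated
#'   (edge values serve as starting points for fixed-at-value edges).
#' @param ft a [freq_table()] with data for every leaf of the graph.
#' @param blocks a [make_blocks()] partition.
#' @param inbreed apply the pseudo-haploid bias correction to the observed
#'   f2/f3 statistics (see [f_statistic()]).
#' @param n_restarts number of random multi-starts for the admixture
#'   proportions (ignored when the graph has none).
#' @param seed seed for the multi-start draws.
#' @param ridge relative ridge for a singular basis covariance.
#' @param weighting `"full"` jackknife covariance or `"diagonal"`
#'   fallback.
#' @param residuals logical; compute the full f2/f3/f4 residual report
#'   (can be disabled for speed inside search loops, leaving `worst_z`
#'   based on the f2 basis only).
#' @return An object of class `graph_fit`: the fitted graph, fitted
#'   `alpha` and `drift` parameters, the GLS `objective`, the residual
#'   table (`kind`, populations, observed, expected, `se`, `z` in
#'   F_ST x 1000 units), `worst_z`, the heterozygosity normalizer
#'   `lambda`, and convergence flags.
#' @export
fit_graph <- function(graph, ft, blocks, inbreed = TRUE, n_restarts = 10,
                      seed = 1L, ridge = 1e-6,
                      weighting = c("full", "diagonal"), residuals = TRUE) {
  weighting <- match.arg(weighting)
  leaves <- graph$leaves
  missing <- setdiff(leaves, ft$pops)
  if (length(missing)) stopf("no data for leaf population(s): %s",
                             paste(missing, collapse = ", "))
  basis <- enumerate_basis(leaves)
  tab <- fstat_block_table(ft, basis, blocks, inbreed = inbreed,
                           want_cov = TRUE)
  lambda <- het_normalizer(ft, leaves)
  u <- 1000 / lambda
  y <- tab$estimate * u
  C <- tab$cov * u^2
  if (weighting == "diagonal") C <- diag(diag(C), nrow(C))
  ri <- regularized_inverse(C, ridge)
  Wh <- chol(ri$inv)                      # whitener: ||Wh (y - mu)||^2
  e <- graph$edges
  drift_idx <- which(e$type == "drift")
  free_drift <- e$free[drift_idx]
  ap <- alpha_params(graph)
  nfree_a <- sum(ap$free)

  pair_i <- vapply(basis, function(s) s$pops[1], "")
  pair_j <- vapply(basis, function(s) s$pops[2], "")

  solve_given_alpha <- function(avec) {
    g2 <- if (nrow(ap)) set_alphas(graph, ap, replace(ap$value, ap$free, avec)) else graph
    w <- leaf_edge_weights(g2)
    M <- (w[pair_i, , drop = FALSE] - w[pair_j, , drop = FALSE])^2
    rhs <- y
    cfull <- e$value[drift_idx]
    if (any(!free_drift))
      rhs <- rhs - M[, !free_drift, drop = FALSE] %*% cfull[!free_drift]
    sol <- nnls_solve(Wh %*% M[, free_drift, drop = FALSE],
                      drop(Wh %*% rhs))
    cfull[free_drift] <- sol$x
    list(obj = sol$obj, c = cfull, w = w, graph = g2)
  }

  if (nfree_a == 0) {
    best <- solve_given_alpha(numeric(0))
    conv <- TRUE
  } else {
    obj_fn <- function(a) solve_given_alpha(a)$obj
    starts <- with_seed(sub_seed(seed, 7L), {
      s0 <- ap$value[ap$free]
      more <- if (n_restarts > 1)
        matrix(runif((n_restarts - 1) * nfree_a, 0.05, 0.95),
               ncol = nfree_a) else NULL
      rbind(matrix(s0, nrow = 1), more)
    })
    best_opt <- NULL
    for (r in seq_len(nrow(starts))) {
      op <- tryCatch(
        optim(starts[r, ], obj_fn, method = "L-BFGS-B", lower = 1e-3,
              upper = 1 - 1e-3, control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best_opt) || op$value < best_opt$value))
        best_opt <- op
    }
    if (is.null(best_opt)) stopf("graph fit failed from every start")
    conv <- best_opt$convergence == 0
    best <- solve_given_alpha(best_opt$par)
  }

  fitted <- best$graph
  fitted$edges$value[drift_idx] <- best$c
  w <- best$w
  ce <- best$c

  stats <- if (residuals) enumerate_residual_stats(leaves) else basis
  rtab <- fstat_block_table(ft, stats, blocks, inbreed = inbreed,
                            want_cov = FALSE)
  expct <- vapply(seq_along(stats), function(i)
    exp_from_w(w, ce, stats[[i]]$kind, stats[[i]]$pops), 0)
  obs <- rtab$estimate * u
  se <- rtab$se * u
  z <- (obs - expct) / se
  res <- data.frame(
    kind = vapply(stats, `[[`, "", "kind"),
    pops = vapply(stats, function(s) paste(s$pops, collapse = ","), ""),
    observed = obs, expected = expct, se = se, z = z)
  res <- res[order(-abs(res$z)), ]
  drift_names <- paste0(e$parent[drift_idx], "->", e$child[drift_idx])
  structure(list(graph = fitted,
                 alpha = if (nrow(ap)) setNames(
                   fitted$edges$value[ap$i1], ap$node) else numeric(0),
                 drift = setNames(ce, drift_names),
                 objective = best$obj, residuals = res,
                 worst_z = max(abs(res$z)), lambda = lambda,
                 units = "F_ST x 1000", inbreed = inbreed,
                 converged = conv, ridged = ri$ridged),
            class = "graph_fit")
}

#' @export
print.graph_fit <- function(x, ...) {
  cat(sprintf("graph_fit: objective %.3f, worst |Z| = %.2f%s\n", x$objective,
              x$worst_z, if (!x$converged) " (not converged)" else ""))
  if (length(x$alpha))
    cat("  admixture proportions:",
        paste(sprintf("%s = %.3f", names(x$alpha), x$alpha), collapse = ", "),
        "\n")
  cat("  largest residuals:\n")
  print(head(x$residuals, 3), row.names = FALSE)
  invisible(x)
}

#' Jackknife uncertainties for fitted graph edge lengths
#'
#' Re-fits the graph with each of `n_blocks` contiguous equal-SNP-count
#' blocks deleted in turn, warm-starting every refit from the full
#' solution, and reports a weighted jackknife standard error and a
#' Z-score from zero for every free drift edge.  A drift length whose
#' Z-score from zero is small indicates that the data do not require any
#' drift on that edge (the diagnostic used to ask whether an admixture
#' source shares real drift with its sister population).
#'
#' @param fit a [fit_graph()] result.
#' @param ft the [freq_table()] the fit used.
#' @param n_blocks number of equal-count jackknife blocks (default 100).
#' @return A data frame with columns `edge`, `estimate`, `se`,
#'   `z_from_zero` and `n_fail` (delete-one refits that failed and were
#'   excluded, with a warning).
#' @export
edge_jackknife <- function(fit, ft, n_blocks = 100) {
  graph <- fit$graph
  leaves <- graph$leaves
  blocks <- make_blocks(ft$snp, "count", n_blocks = n_blocks)
  basis <- enumerate_basis(leaves)
  tab <- fstat_block_table(ft, basis, blocks, inbreed = fit$inbreed,
                           want_cov = TRUE)
  u <- 1000 / fit$lambda
  Cw <- tab$cov * u^2
  ri <- regularized_inverse(Cw)
  Wh <- chol(ri$inv)                      # reused across delete-one refits
  e <- graph$edges
  drift_idx <- which(e$type == "drift")
  free_drift <- e$free[drift_idx]
  ap <- alpha_params(graph)
  nfree_a <- sum(ap$free)
  pair_i <- vapply(basis, function(s) s$pops[1], "")
  pair_j <- vapply(basis, function(s) s$pops[2], "")

  refit <- function(yv) {
    solve_a <- function(avec) {
      g2 <- if (nrow(ap)) set_alphas(graph, ap, replace(ap$value, ap$free, avec)) else graph
      w <- leaf_edge_weights(g2)
      M <- (w[pair_i, , drop = FALSE] - w[pair_j, , drop = FALSE])^2
      rhs <- yv
      cfull <- e$value[drift_idx]
      if (any(!free_drift))
        rhs <- rhs - M[, !free_drift, drop = FALSE] %*% cfull[!free_drift]
      sol <- nnls_solve(Wh %*% M[, free_drift, drop = FALSE],
                        drop(Wh %*% rhs))
      cfull[free_drift] <- sol$x
      list(obj = sol$obj, c = cfull)
    }
    if (nfree_a == 0) return(solve_a(numeric(0))$c)
    a0 <- ap$value[ap$free]
    op <- optim(a0, function(a) solve_a(a)$obj, method = "L-BFGS-B",
                lower = 1e-3, upper = 1 - 1e-3,
                control = list(factr = 1e6))
    solve_a(op$par)$c
  }

  g <- blocks$n_blocks
  wblk <- rowSums(tab$weights)
  full_c <- fit$drift
  loo <- matrix(NA_real_, g, length(drift_idx))
  fails <- 0L
  for (j in seq_len(g)) {
    cj <- tryCatch(refit(tab$loo[j, ] * u), error = function(err) NULL)
    if (is.null(cj)) fails <- fails + 1L else loo[j, ] <- cj
  }
  if (fails > 0)
    warnf("%d of %d delete-one refits failed; SEs computed over successes",
          fails, g)
  ok <- !is.na(loo[, 1])
  out <- lapply(which(free_drift), function(i) {
    jk <- jackknife_from_loo(full_c[[i]], loo[ok, i], wblk[ok])
    data.frame(edge = names(full_c)[i], estimate = full_c[[i]], se = jk$se,
               z_from_zero = if (jk$se > 0) full_c[[i]] / jk$se else 0,
               n_fail = fails)
  })
  do.call(rbind, out)
}

#' Compare a graph with and without an extra admixture edge
#'
#' Fits the base graph and the graph extended with one admixture event
#' (see [add_admixture_edge()]) and applies the decision rule: the extra
#' edge is accepted when it decreases the maximum residual |Z| by more
#' than `delta` (default 0.3).
#'
#' @param graph the base [admixture_graph()].
#' @param dest_edge,src_edge the drift edges (as `c(parent, child)`)
#'   defining the extra admixture event.
#' @param ft a [freq_table()].
#' @param blocks a [make_blocks()] partition.
#' @param delta acceptance threshold on the drop in maximum |Z|.
#' @param alpha initial proportion for the new event.
#' @param ... further arguments to [fit_graph()].
#' @return A list with `base_fit`, `extended_fit`, `delta_max_z`
#'   (base worst |Z| minus extended worst |Z|) and `accept`.
#' @export
compare_with_edge <- function(graph, dest_edge, src_edge, ft, blocks,
                              delta = 0.3, alpha = 0.5, ...) {
  base_fit <- fit_graph(graph, ft, blocks, ...)
  ext <- add_admixture_edge(graph, dest_edge, src_edge, alpha = alpha,
                            tag = "xadm")
  ext_fit <- fit_graph(ext, ft, blocks, ...)
  dz <- base_fit$worst_z - ext_fit$worst_z
  list(base_fit = base_fit, extended_fit = ext_fit, delta_max_z = dz,
       accept = dz > delta)
}

# Canonical (deterministic) ordering of a graph's drift edges.
canonical_drift_edges <- function(graph) {
  e <- graph$edges
  i <- which(e$type == "drift")
  i[order(e$parent[i], e$child[i])]
}

attach_clade <- function(graph, edge_row, leaf, init_drift = 10) {
  e <- graph$edges
  x <- paste0("g_", leaf, "_", e$parent[edge_row], "_", e$child[edge_row])
  new <- rbind(
    data.frame(parent = e$parent[edge_row], child = x, type = "drift",
               value = e$value[edge_row] / 2, free = TRUE),
    data.frame(parent = x, child = e$child[edge_row], type = "drift",
               value = e$value[edge_row] / 2, free = TRUE),
    data.frame(parent = x, child = leaf, type = "drift",
               value = init_drift, free = TRUE))
  admixture_graph(rbind(e[-edge_row, ], new))
}

attach_admixed_leaf <- function(graph, row1, row2, leaf, alpha = 0.5,
                                init_drift = 10) {
  e <- graph$edges
  x1 <- paste0("g_", leaf, "_a"); x2 <- paste0("g_", leaf, "_b")
  mx <- paste0("g_", leaf, "_m")
  split_edge <- function(row, x)
    rbind(data.frame(parent = e$parent[row], child = x, type = "drift",
                     value = e$value[row] / 2, free = TRUE),
          data.frame(parent = x, child = e$child[row], type = "drift",
                     value = e$value[row] / 2, free = TRUE))
  new <- rbind(split_edge(row1, x1), split_edge(row2, x2),
               data.frame(parent = x1, child = mx, type = "admix",
                          value = 1 - alpha, free = TRUE),
               data.frame(parent = x2, child = mx, type = "admix",
                          value = alpha, free = TRUE),
               data.frame(parent = mx, child = leaf, type = "drift",
                          value = init_drift, free = TRUE))
  admixture_graph(rbind(e[-c(row1, row2), ], new))
}

#' Greedy graft search for admixture-graph extensions
#'
#' Starting from a fitting skeleton graph, candidate populations are
#' grafted one at a time in input order.  Each candidate is first tried as
#' an unadmixed clade on every drift edge (minimizing graph complexity);
#' placements whose fit keeps the worst residual |Z| at or below `z_max`
#' are retained.  Only if no clade placement fits are all 2-way admixed
#' placements (pairs of attachment edges) tried.  The search is
#' deterministic given the candidate order, a canonical attachment-edge
#' ordering, and the fit seed; surviving graphs are ordered by number of
#' admixture events, then worst |Z|.
#'
#' @param skeleton a fitting [admixture_graph()].
#' @param candidates character vector of population labels to graft.
#' @param ft a [freq_table()] with data for skeleton leaves and
#'   candidates.
#' @param blocks a [make_blocks()] partition.
#' @param z_max fit-retention threshold on the worst residual |Z|
#'   (default 3.5).
#' @param max_graphs beam width: maximum number of fitting graphs carried
#'   to the next candidate.
#' @param ... further arguments to [fit_graph()].
#' @return A list with `graphs` (each element: `graph`, `fit`, `history`
#'   of placements) and `skipped` (candidates with no fitting placement).
#' @export
graft_search <- function(skeleton, candidates, ft, blocks, z_max = 3.5,
                         max_graphs = 20, ...) {
  skel_fit <- fit_graph(skeleton, ft, blocks, ...)
  if (skel_fit$worst_z > z_max)
    stopf("skeleton does not fit (worst |Z| = %.2f > %.2f)",
          skel_fit$worst_z, z_max)
  states <- list(list(graph = skeleton, fit = skel_fit,
                      history = character(0)))
  skipped <- character(0)
  for (cand in candidates) {
    found <- list()
    for (st in states) {
      rows <- canonical_drift_edges(st$graph)
      e <- st$graph$edges
      for (r in rows) {
        g2 <- tryCatch(attach_clade(st$graph, r, cand),
                       error = function(err) NULL)
        if (is.null(g2)) next
        f2 <- tryCatch(fit_graph(g2, ft, blocks, ...),
                       error = function(err) NULL)
        if (!is.null(f2) && f2$worst_z <= z_max)
          found[[length(found) + 1L]] <- list(
            graph = f2$graph, fit = f2,
            history = c(st$history,
                        sprintf("%s as clade on %s->%s", cand,
                                e$parent[r], e$child[r])))
      }
    }
    if (!length(found)) {
      for (st in states) {
        rows <- canonical_drift_edges(st$graph)
        e <- st$graph$edges
        for (a in seq_along(rows)) for (b in seq_along(rows)) {
          if (a >= b) next
          g2 <- tryCatch(attach_admixed_leaf(st$graph, rows[a], rows[b],
                                             cand),
                         error = function(err) NULL)
          if (is.null(g2)) next
          f2 <- tryCatch(fit_graph(g2, ft, blocks, ...),
                         error = function(err) NULL)
          if (!is.null(f2) && f2$worst_z <= z_max)
            found[[length(found) + 1L]] <- list(
              graph = f2$graph, fit = f2,
              history = c(st$history,
                          sprintf("%s as mixture of %s->%s and %s->%s",
                                  cand, e$parent[rows[a]], e$child[rows[a]],
                                  e$parent[rows[b]], e$child[rows[b]])))
        }
      }
    }
    if (!length(found)) {
      skipped <- c(skipped, cand)
      next
    }
    n_adm <- vapply(found, function(s) sum(s$graph$edges$type == "admix") / 2, 0)
    wz <- vapply(found, function(s) s$fit$worst_z, 0)
    att <- vapply(found, function(s) s$history[length(s$history)], "")
    states <- found[order(n_adm, wz, att)]
    if (length(states) > max_graphs) states <- states[seq_len(max_graphs)]
  }
  list(graphs = states, skipped = skipped)
}
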