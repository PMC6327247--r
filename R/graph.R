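# Admixture graphs: representation, prediction of expected f-statistics,
# and a plain-text edge-list serialization.
#
# A graph is a rooted DAG.  Drift edges carry a length c_e in F_ST x 1000
# units; an admixture node has exactly two incoming "admix" edges whose
# values are the mixture proportions (alpha, 1 - alpha) and which carry no
# drift.  Leaves are named directly after the populations they represent.

#' Construct an admixture graph
#'
#' @param edges data frame with columns `parent`, `child`, `type`
#'   (`"drift"` or `"admix"`), `value` (drift length in F_ST x 1000 units,
#'   or mixture proportion), and optionally `free` (logical; free
#'   parameters are re-estimated by [fit_graph()], fixed ones are kept).
#'   `free` defaults to `TRUE` for every edge.
#' @return An object of class `admixture_graph` with derived `nodes`,
#'   `root` and `leaves` fields.
#' @export
admixture_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child", "type", "value") %in% names(edges)))
    stopf("edges need parent, child, type, value columns")
  if (is.null(edges$free)) edges$free <- TRUE
  if (!all(edges$type %in% c("drift", "admix")))
    stopf("edge type must be 'drift' or 'admix'")
  if (any(edges$type == "drift" & edges$value < 0))
    stopf("drift edge lengths must be nonnegative")
  nodes <- unique(c(edges$parent, edges$child))
  n_in_drift <- table(factor(edges$child[edges$type == "drift"], levels = nodes))
  n_in_admix <- table(factor(edges$child[edges$type == "admix"], levels = nodes))
  n_in <- n_in_drift + n_in_admix
  roots <- nodes[n_in == 0]
  if (length(roots) != 1L)
    stopf("graph must have exactly one root, found: %s",
          paste(roots, collapse = ", "))
  bad <- nodes[!(n_in %in% c(0, 1) | (n_in == 2 & n_in_admix == 2))]
  if (length(bad))
    stopf("node(s) with invalid in-edges (need 1 drift parent or 2 admix parents): %s",
          paste(bad, collapse = ", "))
  for (v in nodes[n_in_admix == 2]) {
    s <- sum(edges$value[edges$type == "admix" & edges$child == v])
    if (abs(s - 1) > 1e-8)
      stopf("admixture proportions into %s sum to %g, not 1", v, s)
  }
  order <- topo_order(edges, nodes, roots)
  leaves <- nodes[!(nodes %in% edges$parent)]
  structure(list(edges = edges, nodes = order, root = roots, leaves = leaves),
            class = "admixture_graph")
}

# Topological order (parents before children); errors on cycles.
topo_order <- function(edges, nodes, root) {
  indeg <- table(factor(edges$child, levels = nodes))
  queue <- nodes[indeg == 0]
  out <- character(0)
  indeg <- as.vector(indeg); names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in edges$child[edges$parent == v]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(nodes))
    stopf("graph contains a cycle involving: %s",
          paste(setdiff(nodes, out), collapse = ", "))
  out
}

#' @export
print.admixture_graph <- function(x, ...) {
  n_adm <- sum(x$edges$type == "admix") / 2
  cat(sprintf("admixture_graph: %d nodes, %d drift edges, %d admixture event(s); leaves: %s\n",
              length(x$nodes), sum(x$edges$type == "drift"), n_adm,
              paste(x$leaves, collapse = ", ")))
  invisible(x)
}

#' Write / read an admixture graph as a plain-text edge list
#'
#' One edge per line: `drift <parent> <child> <length> <free|fixed>` or
#' `admix <parent> <child> <proportion> <free|fixed>`.  Values are written
#' with 17 significant digits so the round trip is lossless.
#'
#' @param graph an `admixture_graph`.
#' @param path file path.
#' @return `write_graph` returns the path invisibly; `read_graph` returns
#'   the graph.
#' @export
write_graph <- function(graph, path) {
  e <- graph$edges
  lines <- sprintf("%s %s %s %.17g %s", e$type, e$parent, e$child, e$value,
                   ifelse(e$free, "free", "fixed"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("type", "parent", "child", "value", "free"))
  admixture_graph(data.frame(parent = tab$parent, child = tab$child,
                             type = tab$type, value = tab$value,
                             free = tab$free == "free"))
}

#' Edge traversal probabilities for each leaf
#'
#' For every leaf and drift edge, the probability that a lineage sampled
#' from the leaf traverses the edge on its way to the root, i.e. the sum
#' over root paths of the products of admixture proportions along the path.
#' This is the linear-model core of expected-f-statistic prediction.
#'
#' @param graph an `admixture_graph`.
#' @return A numeric matrix, leaves in rows, one column per drift edge
#'   (named `parent->child`).
#' @export
leaf_edge_weights <- function(graph) {
  nodes <- graph$nodes
  leaves <- graph$leaves
  e <- graph$edges
  W <- matrix(0, length(leaves), length(nodes),
              dimnames = list(leaves, nodes))
  W[cbind(leaves, leaves)] <- 1
  # children before parents
  for (v in rev(nodes)) {
    inc <- which(e$child == v)
    for (i in inc) {
      m <- if (e$type[i] == "admix") e$value[i] else 1
      W[, e$parent[i]] <- W[, e$parent[i]] + m * W[, v]
    }
  }
  drift <- which(e$type == "drift")
  out <- W[, e$child[drift], drop = FALSE]
  colnames(out) <- paste0(e$parent[drift], "->", e$child[drift])
  rownames(out) <- leaves
  out
}

#' Expected f-statistics under an admixture graph
#'
#' `expected_f2(A, B)` is the quadratic form `sum_e (w_A(e) - w_B(e))^2
#' c_e` over drift edges, where `w_X(e)` are the traversal probabilities of
#' [leaf_edge_weights()]; this is the standard small-drift linearization.
#' Expected f3 and f4 are derived from f2 through the identities
#' `f3(C; A, B) = (f2(C,A) + f2(C,B) - f2(A,B)) / 2` and
#' `f4(A,B; C,D) = (f2(A,D) + f2(B,C) - f2(A,C) - f2(B,D)) / 2`, so the
#' model-side statistics are internally consistent by construction.
#'
#' @param graph an `admixture_graph`.
#' @param leafA,leafB leaf names.
#' @return Expected statistic in F_ST x 1000 units.
#' @export
expected_f2 <- function(graph, leafA, leafB) {
  w <- leaf_edge_weights(graph)
  for (l in c(leafA, leafB))
    if (!l %in% rownames(w)) stopf("unknown leaf: %s", l)
  e <- graph$edges
  c_e <- e$value[e$type == "drift"]
  sum((w[leafA, ] - w[leafB, ])^2 * c_e)
}

#' @rdname expected_f2
#' @param kind one of `"f2"`, `"f3"`, `"f4"`.
#' @param pops character vector of 2, 3 (C, A, B) or 4 (A, B, C, D) leaves.
#' @export
expected_fstat <- function(graph, kind, pops) {
  w <- leaf_edge_weights(graph)
  e2 <- function(a, b) expected_f2_w(w, graph, a, b)
  switch(kind,
    f2 = e2(pops[1], pops[2]),
    f3 = (e2(pops[1], pops[2]) + e2(pops[1], pops[3]) -
            e2(pops[2], pops[3])) / 2,
    f4 = (e2(pops[1], pops[4]) + e2(pops[2], pops[3]) -
            e2(pops[1], pops[3]) - e2(pops[2], pops[4])) / 2,
    stopf("unknown kind: %s", kind))
}

expected_f2_w <- function(w, graph, a, b) {
  e <- graph$edges
  c_e <- e$value[e$type == "drift"]
  sum((w[a, ] - w[b, ])^2 * c_e)
}

#' Insert an admixture event into a graph
#'
#' Rewires the drift edge `dest_edge` (a `c(parent, child)` pair) so that
#' its child lineage becomes a 2-way mixture: a new admixture node receives
#' one admix edge from a new node inserted on `dest_edge` and one from a
#' new node inserted on `src_edge`.  Existing drift lengths are split in
#' half across the inserted nodes; all new parameters are free.
#'
#' @param graph an `admixture_graph`.
#' @param dest_edge,src_edge length-2 character vectors naming existing
#'   drift edges by `c(parent, child)`.
#' @param alpha initial mixture proportion assigned to the `src_edge` side.
#' @param tag string used to name the inserted nodes.
#' @return A new `admixture_graph`.
#' @export
add_admixture_edge <- function(graph, dest_edge, src_edge, alpha = 0.5,
                               tag = "adm") {
  e <- graph$edges
  find_edge <- function(pe) {
    i <- which(e$type == "drift" & e$parent == pe[1] & e$child == pe[2])
    if (length(i) != 1L) stopf("no drift edge %s -> %s", pe[1], pe[2])
    i
  }
  id <- find_edge(dest_edge); is <- find_edge(src_edge)
  if (id == is) stopf("dest_edge and src_edge must differ")
  nd <- paste0(tag, "_d"); ns <- paste0(tag, "_s"); nm <- paste0(tag, "_m")
  if (any(c(nd, ns, nm) %in% graph$nodes))
    stopf("node name clash for tag '%s'", tag)
  rows <- function(parent, child, type, value, free)
    data.frame(parent = parent, child = child, type = type, value = value,
               free = free)
  new <- rbind(
    rows(e$parent[id], nd, "drift", e$value[id] / 2, TRUE),
    rows(e$parent[is], ns, "drift", e$value[is] / 2, TRUE),
    rows(ns, e$child[is], "drift", e$value[is] / 2, TRUE),
    rows(nd, nm, "admix", 1 - alpha, TRUE),
    rows(ns, nm, "admix", alpha, TRUE),
    rows(nm, e$child[id], "drift", e$value[id] / 2, TRUE))
  admixture_graph(rbind(e[-c(id, is), ], new))
}
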