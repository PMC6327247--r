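# Low-dimensional views: PCA with least-squares projection of
# low-coverage samples, and MDS / neighbor-joining trees from an
# outgroup-f3 shared-drift matrix.

#' Fit a PCA model on reference samples
#'
#' Principal components are computed from the reference (typically
#' present-day, diploid) samples only.  Genotypes are mean-centered per
#' SNP and scaled by the binomial standard deviation `sqrt(p (1 - p))`
#' with the shrunk frequency estimate `p = (1 + sum g) / (2 + 2 n)`
#' (the small-sample shrinkage keeps rare variants from exploding the
#' scale).  SNPs with zero variance or more than `max_missing` missing
#' reference genotypes are dropped; remaining missing reference entries
#' are mean-imputed.
#'
#' @param dataset a [genotype_dataset()].
#' @param reference_samples sample ids used to compute the components.
#' @param k number of components (must not exceed the usable dimension).
#' @param max_missing maximum missing fraction for a SNP to be retained.
#' @return An object of class `pca_model` with the retained SNP ids,
#'   per-SNP centers and scales, SNP loadings, eigenvalues, and the
#'   reference coordinates.
#' @export
pca_fit <- function(dataset, reference_samples, k, max_missing = 0.5) {
  idx <- match(reference_samples, dataset$sample$sample_id)
  if (anyNA(idx)) stopf("unknown reference sample(s): %s",
                        paste(reference_samples[is.na(idx)], collapse = ", "))
  if (length(idx) < k + 1) stopf("need at least k + 1 reference samples")
  G <- dataset$geno[idx, , drop = FALSE]
  nval <- colSums(!is.na(G))
  mu <- colMeans(G, na.rm = TRUE)
  p <- (1 + colSums(G, na.rm = TRUE)) / (2 + 2 * nval)
  keep <- nval >= (1 - max_missing) * length(idx) & nval > 0 &
    apply(G, 2, function(col) {
      v <- col[!is.na(col)]; length(unique(v)) > 1
    })
  if (sum(keep) < k) stopf("k = %d exceeds the usable dimension %d", k, sum(keep))
  G <- G[, keep, drop = FALSE]
  mu <- mu[keep]; scale <- sqrt(p[keep] * (1 - p[keep]))
  Z <- sweep(sweep(G, 2, mu, "-"), 2, scale, "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = k)
  if (k > length(sv$d)) stopf("k = %d exceeds the usable dimension", k)
  structure(list(snp_ids = dataset$snp$snp_id[keep], center = mu,
                 scale = scale, loadings = sv$v,
                 eigenvalues = sv$d[seq_len(k)]^2 / (length(idx) - 1),
                 ref_coords = sv$u %*% diag(sv$d[seq_len(k)], k),
                 ref_samples = reference_samples, k = k),
            class = "pca_model")
}

#' Project a sample onto fitted principal components by least squares
#'
#' Solves the over-determined system restricted to the sample's
#' non-missing SNPs, so low-coverage samples are placed without imputing
#' their missing genotypes.  Projections with fewer than `min_overlap`
#' overlapping SNPs are flagged unreportable.
#'
#' @param pca_model a [pca_fit()] result.
#' @param sample_genotypes named integer vector (names = SNP ids, values
#'   0/1/2/NA) or a 1-row slice of a genotype matrix.
#' @param min_overlap reporting threshold on overlapping SNPs (default
#'   10000).
#' @return An object of class `pca_projection` with `coords`,
#'   `n_overlap` and `reportable`.
#' @export
lsq_project <- function(pca_model, sample_genotypes, min_overlap = 10000) {
  g <- sample_genotypes[pca_model$snp_ids]
  obs <- which(!is.na(g))
  if (!length(obs)) stopf("sample has zero overlap with the PCA SNP set")
  z <- (g[obs] - pca_model$center[obs]) / pca_model$scale[obs]
  V <- pca_model$loadings[obs, , drop = FALSE]
  coords <- drop(qr.solve(V, z))
  structure(list(coords = coords, n_overlap = length(obs),
                 reportable = length(obs) >= min_overlap),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("projection on %d PCs from %d SNPs%s: %s\n", length(x$coords),
              x$n_overlap,
              if (!x$reportable) " [below reporting threshold]" else "",
              paste(sprintf("%.4f", x$coords), collapse = ", ")))
  invisible(x)
}

#' Classical MDS of an outgroup-f3 matrix
#'
#' Converts shared drift to dissimilarity by `d_ij = 1 - f3(O; i, j)` and
#' applies classical (Torgerson) metric scaling; coordinates are centered
#' at the origin.
#'
#' @param f3_matrix an [outgroup_f3_matrix()] result.
#' @param k number of dimensions (default 2).
#' @return A matrix of per-population coordinates.
#' @export
mds_from_f3 <- function(f3_matrix, k = 2) {
  V <- f3_matrix$values
  off <- upper.tri(V)
  if (any(is.na(V[off])))
    stopf("missing f3 cells for pair(s): %s", paste(
      apply(which(is.na(V) & off, arr.ind = TRUE), 1, function(ij)
        paste(f3_matrix$pops[ij], collapse = "/")), collapse = ", "))
  d <- 1 - V
  diag(d) <- 0
  coords <- cmdscale(as.dist(d), k = k)
  rownames(coords) <- f3_matrix$pops
  coords
}

#' Neighbor-joining tree from an outgroup-f3 matrix
#'
#' Builds distances `d_ij = 1 / f3(O; i, j)`, runs neighbor joining, and
#' roots the tree on the designated outgroup.  Negative branch lengths
#' (possible when distances are not additive) are clamped to zero with
#' the deficit moved onto the adjacent branches, the standard display
#' convention.
#'
#' @param f3_matrix an [outgroup_f3_matrix()] result with strictly
#'   positive entries.
#' @param outgroup_label population on which to root the tree (must be one
#'   of the matrix populations).
#' @return A Newick string with branch lengths.
#' @export
nj_from_f3 <- function(f3_matrix, outgroup_label) {
  V <- f3_matrix$values
  off <- upper.tri(V)
  bad <- which((is.na(V) | V <= 0) & off, arr.ind = TRUE)
  if (nrow(bad))
    stopf("nonpositive or missing f3 for pair(s): %s", paste(
      apply(bad, 1, function(ij) paste(f3_matrix$pops[ij], collapse = "/")),
      collapse = ", "))
  if (!outgroup_label %in% f3_matrix$pops)
    stopf("outgroup %s is not in the matrix", outgroup_label)
  d <- 1 / V
  diag(d) <- 0
  dimnames(d) <- list(f3_matrix$pops, f3_matrix$pops)
  tree <- ape::nj(as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (i in neg) {
    deficit <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    child <- tree$edge[i, 2]
    adj <- which(tree$edge[, 1] == child)
    tree$edge.length[adj] <- tree$edge.length[adj] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  ape::write.tree(tree)
}
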