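# Population structure: allele-frequency PCA, IBS distances, NJ tree.

#' Principal component analysis of genotype dosages
#'
#' Missing calls are replaced by the variant mean, each variant is centered
#' at twice its allele frequency and (by default) divided by the binomial
#' standard deviation `sqrt(2 p (1-p))` -- the Patterson/EIGENSTRAT scaling
#' under which drift contributes equally across frequencies. Monomorphic
#' variants have zero scale and are dropped with a message. The sample-by-
#' sample covariance is then eigendecomposed.
#'
#' @param g A [genotype_matrix()] with at least 2 samples and 2 variants.
#' @param n_components Number of components to return.
#' @param scaling `"patterson"` (default), `"unit"` (per-variant standard
#'   deviation) or `"none"` (centering only).
#' @return A `pca_result`: list with `coordinates` (samples x components,
#'   each column scaled so its variance is proportional to its eigenvalue),
#'   `variance_explained` (eigenvalue fractions over all components),
#'   `n_dropped_monomorphic`, and the sample table.
#' @export
pca_genotypes <- function(g, n_components = 10,
                          scaling = c("patterson", "unit", "none")) {
  stopifnot(inherits(g, "genotype_matrix"))
  scaling <- match.arg(scaling)
  if (nrow(g$calls) < 2 || ncol(g$calls) < 2) {
    stopf("PCA needs at least 2 samples and 2 variants")
  }
  x <- g$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss)) x[miss] <- mu[miss[, 2]]

  p <- mu / 2
  scale <- switch(scaling,
    patterson = sqrt(2 * p * (1 - p)),
    unit = apply(x, 2, stats::sd),
    none = rep(1, ncol(x))
  )
  mono <- !is.finite(scale) | scale <= 0
  if (any(mono)) {
    message(sprintf("dropping %d monomorphic variant(s) from PCA", sum(mono)))
    x <- x[, !mono, drop = FALSE]
    mu <- mu[!mono]
    scale <- scale[!mono]
  }
  if (ncol(x) < 2) stopf("fewer than 2 polymorphic variants for PCA")
  xs <- sweep(sweep(x, 2, mu, "-"), 2, scale, "/")
  cv <- tcrossprod(xs) / ncol(xs)
  eig <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  k <- min(n_components, length(lambda))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)]), k)
  dimnames(coords) <- list(g$samples$sample_id, paste0("PC", seq_len(k)))
  structure(
    list(
      coordinates = coords,
      variance_explained = lambda / sum(lambda),
      n_dropped_monomorphic = sum(mono),
      samples = g$samples
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  k <- min(5, ncol(x$coordinates))
  cat(sprintf(
    "PCA of %d samples; leading components explain %s of variance\n",
    nrow(x$coordinates),
    paste(sprintf("%.1f%%", 100 * ve[seq_len(k)]), collapse = ", ")
  ))
  invisible(x)
}

#' Pairwise identity-by-state distance matrix
#'
#' For each sample pair, over the variants called in both, the similarity is
#' the fraction of shared alleles (per variant `2 - |d_i - d_j|` of 2); the
#' IBS distance is one minus that fraction.
#'
#' @param g A [genotype_matrix()] with at least two samples.
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, entries in \[0, 1\].
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$calls) < 2) stopf("need at least two samples")
  m <- g$calls
  ind <- lapply(0:2, function(v) {
    x <- m == v
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  # counts of variants where sample i carries dosage a and j carries b
  nab <- function(a, b) tcrossprod(ind[[a + 1L]], ind[[b + 1L]])
  diffsum <- nab(0, 1) + nab(1, 0) + nab(1, 2) + nab(2, 1) +
    2 * (nab(0, 2) + nab(2, 0))
  called <- tcrossprod(
    ind[[1]] + ind[[2]] + ind[[3]]
  )
  if (any(called[upper.tri(called)] == 0)) {
    w <- which(called == 0 & upper.tri(called), arr.ind = TRUE)[1, ]
    stopf(
      "samples '%s' and '%s' share no jointly called variant",
      g$samples$sample_id[w[1]], g$samples$sample_id[w[2]]
    )
  }
  d <- diffsum / (2 * called)
  diag(d) <- 0
  dimnames(d) <- list(g$samples$sample_id, g$samples$sample_id)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion, via [ape::nj()]) on
#' a symmetric distance matrix, returning an unrooted `phylo`. Negative
#' branch lengths -- an artifact NJ can produce on noisy distances -- are
#' clamped to zero with the deficit transferred to the sibling branch, so
#' path lengths through the parent node are preserved.
#'
#' @param d Symmetric non-negative distance matrix with labels as dimnames
#'   (e.g. from [ibs_distance()]), at least 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stopf("neighbor-joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stopf("distance matrix must be symmetric")
  }
  if (any(d < 0)) stopf("distances must be non-negative")
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

# set negative edge lengths to 0, adding the deficit to a sibling edge
# (first sibling under the same parent), so cophenetic distances through
# the parent are unchanged
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree
}

#' Write a tree in Newick format
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write PCA coordinates and variance explained as TSVs
#' @param pca A `pca_result` from [pca_genotypes()].
#' @param coords_path,variance_path Output paths.
#' @return Invisible character vector of the two paths.
#' @export
write_pca <- function(pca, coords_path, variance_path) {
  df <- data.frame(
    sample_id = rownames(pca$coordinates),
    population = pca$samples$population,
    pca$coordinates,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(df, coords_path)
  write_tsv(
    data.frame(
      component = paste0("PC", seq_along(pca$variance_explained)),
      variance_explained = pca$variance_explained
    ),
    variance_path
  )
  invisible(c(coords_path, variance_path))
}

#' Write a square distance matrix as a labelled TSV
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
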