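# Linkage disequilibrium: pairwise r2, binned decay curves, r2_0.3.

#' Pairwise r-squared between nearby variants
#'
#' Composite (genotype-correlation) LD: for each same-chromosome variant
#' pair within `max_dist`, r2 is the squared Pearson correlation of the two
#' dosage vectors over the samples called at both variants. Pairs where
#' either variant is monomorphic in the jointly called subset (or with
#' fewer than 2 complete samples) are skipped and counted.
#'
#' @param g A [genotype_matrix()] with variants sorted by (chrom, pos).
#' @param max_dist Maximum pair distance in bp (default 500 kb).
#' @return `data.frame(chrom, vid_i, vid_j, distance, r2, n)` where `n` is
#'   the number of jointly called samples; the number of skipped monomorphic
#'   pairs is attached as attribute `n_skipped`.
#' @export
pairwise_r2 <- function(g, max_dist = 5e5) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  check_variants_sorted(v)
  out <- list()
  n_skipped <- 0L
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) < 2) next
    pos <- v$pos[idx]
    x <- g$calls[, idx, drop = FALSE]
    storage.mode(x) <- "double"
    mcal <- !is.na(x)
    x0 <- x
    x0[!mcal] <- 0
    x2 <- x0^2
    mcal <- mcal * 1
    m <- length(idx)
    block <- 512L
    for (a0 in seq(1L, m, by = block)) {
      a1 <- min(a0 + block - 1L, m)
      jmax <- findInterval(pos[a1] + max_dist, pos)
      if (jmax <= a0) next
      ai <- a0:a1
      bi <- a0:jmax
      n <- crossprod(mcal[, ai, drop = FALSE], mcal[, bi, drop = FALSE])
      sx <- crossprod(x0[, ai, drop = FALSE], mcal[, bi, drop = FALSE])
      sy <- crossprod(mcal[, ai, drop = FALSE], x0[, bi, drop = FALSE])
      sxy <- crossprod(x0[, ai, drop = FALSE], x0[, bi, drop = FALSE])
      sxx <- crossprod(x2[, ai, drop = FALSE], mcal[, bi, drop = FALSE])
      syy <- crossprod(mcal[, ai, drop = FALSE], x2[, bi, drop = FALSE])
      covn <- n * sxy - sx * sy
      vx <- n * sxx - sx^2
      vy <- n * syy - sy^2
      ii <- matrix(ai, nrow = length(ai), ncol = length(bi))
      jj <- matrix(bi, nrow = length(ai), ncol = length(bi), byrow = TRUE)
      dist <- pos[jj] - pos[ii]
      keep <- jj > ii & dist <= max_dist
      mono <- keep & (n < 2 | vx <= 0 | vy <= 0)
      n_skipped <- n_skipped + sum(mono)
      keep <- keep & !mono
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        vid_i = v$vid[idx[ii[keep]]],
        vid_j = v$vid[idx[jj[keep]]],
        distance = dist[keep],
        r2 = (covn[keep]^2) / (vx[keep] * vy[keep]),
        n = n[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(
      chrom = character(), vid_i = character(), vid_j = character(),
      distance = numeric(), r2 = numeric(), n = numeric(),
      stringsAsFactors = FALSE
    )
  }
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Bin pairwise r-squared into an LD-decay curve
#'
#' @param pairs Output of [pairwise_r2()] (or any data.frame with
#'   `distance` and `r2`).
#' @param bin_width Bin width in bp; bins are `[k w, (k+1) w)`.
#' @param max_dist Right edge of the last bin; defaults to the largest
#'   observed distance rounded up to a bin boundary.
#' @param population Optional label stored on the curve.
#' @return `data.frame(bin_start, bin_end, mean_r2, n_pairs)`; bins with no
#'   pairs carry `n_pairs = 0` and `mean_r2 = NA` (flagged, not
#'   interpolated).
#' @export
decay_curve <- function(pairs, bin_width = 1e3, max_dist = NULL,
                        population = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(max_dist)) {
    max_dist <- if (nrow(pairs)) {
      bin_width * ceiling(max(pairs$distance) / bin_width)
    } else {
      bin_width
    }
  }
  nbin <- max(1L, ceiling(max_dist / bin_width))
  edges <- (0:nbin) * bin_width
  bin <- pmin(nbin, floor(pairs$distance / bin_width) + 1L)
  mean_r2 <- rep(NA_real_, nbin)
  n_pairs <- integer(nbin)
  if (nrow(pairs)) {
    agg_n <- tapply(pairs$r2, bin, length)
    agg_m <- tapply(pairs$r2, bin, mean)
    at <- as.integer(names(agg_n))
    n_pairs[at] <- agg_n
    mean_r2[at] <- agg_m
  }
  out <- data.frame(
    bin_start = edges[-(nbin + 1L)],
    bin_end = edges[-1L],
    mean_r2 = mean_r2,
    n_pairs = n_pairs
  )
  attr(out, "population") <- population
  out
}

#' Distance at which LD decays below a threshold
#'
#' Returns the left edge of the first bin whose mean r2 is below the
#' threshold *and* that is never exceeded again in any later occupied bin
#' (a persistence rule that ignores noise-driven early dips). If the first
#' occupied bin already qualifies the result is its left edge (0 for the
#' first bin); if no bin qualifies, `NA` is returned ("not reached").
#'
#' @param curve A [decay_curve()] data.frame.
#' @param threshold r2 threshold, default 0.3 (the r2_0.3 statistic).
#' @return Distance in bp, or `NA_real_` if the threshold is never reached.
#' @export
r2_threshold_distance <- function(curve, threshold = 0.3) {
  occ <- which(curve$n_pairs > 0)
  if (!length(occ)) stopf("decay curve has no occupied bins")
  below <- curve$mean_r2[occ] < threshold
  # suffix-true: all occupied bins from here on are below the threshold
  ok <- rev(cumprod(rev(below))) > 0
  if (!any(ok)) {
    return(NA_real_)
  }
  curve$bin_start[occ[which(ok)[1]]]
}

#' Downsample one population to n samples
#'
#' Uniform sampling without replacement within the named population; other
#' populations are untouched. Used to equalize sample sizes before LD
#' comparisons, since r2 estimates are biased upward at small n.
#'
#' @param g A [genotype_matrix()].
#' @param population Population label to downsample.
#' @param n Target sample count (must not exceed the population size).
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with the population reduced to `n`
#'   samples, original sample order preserved.
#' @export
downsample <- function(g, population, n, seed = 1L) {
  idx <- pop_index(g, population)
  if (n > length(idx)) {
    stopf(
      "population '%s' has %d samples, cannot take %d",
      population, length(idx), n
    )
  }
  keep_pop <- with_seed(seed, sort(sample(idx, n)))
  keep <- sort(c(setdiff(seq_len(nrow(g$calls)), idx), keep_pop))
  subset_genotypes(g, samples = keep)
}

#' Per-population LD decay curve
#'
#' Convenience wrapper: restrict to one population, compute [pairwise_r2()]
#' and bin with [decay_curve()].
#'
#' @inheritParams pairwise_r2
#' @inheritParams decay_curve
#' @param population Population label.
#' @return A [decay_curve()] data.frame with the population attribute set.
#' @export
ld_decay <- function(g, population, max_dist = 5e5, bin_width = 1e3) {
  gp <- subset_genotypes(g, samples = pop_index(g, population))
  pairs <- pairwise_r2(gp, max_dist = max_dist)
  decay_curve(pairs,
    bin_width = bin_width, max_dist = max_dist,
    population = population
  )
}
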