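# Sliding-window selective-sweep scan: FST, nucleotide diversity, the
# diversity ratio, min-max scaling, empirical 1% thresholds and sweep calls.
#
# The differentiation statistic is the heterozygosity-based fixation index
# FST = (Ht - Hs) / Ht, with Hs the average expected heterozygosity of the
# two subpopulations and Ht the expected heterozygosity of the pooled
# frequency; windows aggregate it as a ratio of sums. A Weir-Cockerham
# variance-components estimator is available as an alternative: the two do
# not estimate the same quantity (with two demes the heterozygosity form
# targets F/(2-F) under pure drift, while Weir-Cockerham targets F itself).

# per-chromosome sliding windows: floor((L - window)/step) + 1 of them
window_grid <- function(chrom_len, window, step) {
  if (chrom_len < window) {
    return(data.frame(start = 1, end = chrom_len))
  }
  starts <- seq(1, chrom_len - window + 1, by = step)
  data.frame(start = starts, end = starts + window - 1)
}

# resolve per-chromosome lengths: user-supplied named vector, single value,
# or the largest observed position
resolve_chrom_len <- function(g, chrom_len) {
  chroms <- unique(g$variants$chrom)
  if (is.null(chrom_len)) {
    vapply(chroms, function(ch) {
      max(g$variants$pos[g$variants$chrom == ch])
    }, 0)
  } else if (length(chrom_len) == 1L && is.null(names(chrom_len))) {
    stats::setNames(rep(chrom_len, length(chroms)), chroms)
  } else {
    if (!all(chroms %in% names(chrom_len))) {
      stopf("chrom_len must name every chromosome present")
    }
    chrom_len[chroms]
  }
}

# Per-SNP building blocks for the windowed statistics.
# For each population: alt frequency among called alleles, called-allele
# count, observed heterozygote frequency; plus per-SNP Hs/Ht and the
# unbiased per-site diversity n/(n-1) * 2p(1-p).
snp_stats <- function(g, pop1, pop2) {
  i1 <- pop_index(g, pop1)
  i2 <- pop_index(g, pop2)
  per_pop <- function(idx) {
    m <- g$calls[idx, , drop = FALSE]
    nc <- 2 * colSums(!is.na(m))
    p <- colSums(m, na.rm = TRUE) / nc
    het <- colMeans(m == 1L, na.rm = TRUE)
    list(nc = nc, p = p, het = het, n_gt = colSums(!is.na(m)))
  }
  s1 <- per_pop(i1)
  s2 <- per_pop(i2)
  pi_site <- function(s) {
    ifelse(s$nc >= 2, s$nc / (s$nc - 1) * 2 * s$p * (1 - s$p), NA_real_)
  }
  hs <- (2 * s1$p * (1 - s1$p) + 2 * s2$p * (1 - s2$p)) / 2
  pbar <- (s1$p + s2$p) / 2
  ht <- 2 * pbar * (1 - pbar)
  fst_ok <- s1$nc >= 2 & s2$nc >= 2
  list(
    pi1 = pi_site(s1), pi2 = pi_site(s2),
    hs = hs, ht = ht, fst_ok = fst_ok,
    p1 = s1$p, p2 = s2$p, het1 = s1$het, het2 = s2$het,
    n1 = s1$n_gt, n2 = s2$n_gt
  )
}

# Weir-Cockerham variance components a (among populations) and a+b+c,
# two-population biallelic case; vectors over SNPs
wc_components <- function(st) {
  n1 <- st$n1
  n2 <- st$n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * st$p1 + n2 * st$p2) / (r * nbar)
  s2 <- (n1 * (st$p1 - pbar)^2 + n2 * (st$p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * st$het1 + n2 * st$het2) / (r * nbar)
  a <- nbar / nc * (
    s2 - 1 / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4)
  )
  b <- nbar / (nbar - 1) * (
    pbar * (1 - pbar) - (r - 1) / r * s2 -
      (2 * nbar - 1) / (4 * nbar) * hbar
  )
  cc <- hbar / 2
  ok <- st$fst_ok & n1 >= 2 & n2 >= 2 & is.finite(nc) & nc > 0
  list(a = a, denom = a + b + cc, ok = ok)
}

# sum per-SNP vectors over windows via prefix sums; values NA-masked by ok
window_sums <- function(pos, values, ok, grid) {
  v <- ifelse(ok & is.finite(values), values, 0)
  cs <- c(0, cumsum(v))
  ccnt <- c(0, cumsum(as.numeric(ok & is.finite(values))))
  lo <- findInterval(grid$start - 0.5, pos) + 1L
  hi <- findInterval(grid$end + 0.5, pos)
  list(sum = cs[hi + 1L] - cs[lo], n = ccnt[hi + 1L] - ccnt[lo])
}

#' Windowed nucleotide diversity for one population
#'
#' Per SNP, with `n_c` called alleles in the population and `p` the
#' alternate-allele frequency among them, the per-site diversity is the
#' unbiased expected heterozygosity `n_c/(n_c - 1) * 2 p (1 - p)`; a
#' window's diversity is the sum over its SNPs divided by the window length
#' in bp. SNPs with fewer than 2 called alleles are skipped.
#'
#' @param g A [genotype_matrix()] with variants sorted by (chrom, pos).
#' @param population Population label.
#' @param window,step Window and step size in bp (`window >= step`).
#' @param chrom_len Chromosome length(s): `NULL` (use the largest observed
#'   position per chromosome), a single value, or a named vector.
#' @return `data.frame(chrom, start, end, n_snps, pi)` with `pi` per bp.
#' @export
window_pi <- function(g, population, window = 5e6, step = 1e5,
                      chrom_len = NULL) {
  scan <- sweep_scan(g,
    pop1 = population, pop2 = NULL, window = window,
    step = step, chrom_len = chrom_len
  )
  scan[, c("chrom", "start", "end", "n_snps", "pi_p1")] |>
    stats::setNames(c("chrom", "start", "end", "n_snps", "pi"))
}

#' Windowed fixation index between two populations
#'
#' @inheritParams window_pi
#' @param pop1,pop2 The two population labels (must differ).
#' @param estimator `"nei"` for the heterozygosity form
#'   `(Ht - Hs)/Ht` aggregated as a ratio of sums, or `"wc"` for the
#'   Weir-Cockerham variance-components estimator (ratio of summed
#'   components).
#' @return `data.frame(chrom, start, end, n_snps, fst)`; windows with a
#'   zero denominator have `fst = NA`.
#' @export
window_fst <- function(g, pop1, pop2, window = 5e6, step = 1e5,
                       chrom_len = NULL, estimator = c("nei", "wc")) {
  estimator <- match.arg(estimator)
  scan <- sweep_scan(g,
    pop1 = pop1, pop2 = pop2, window = window, step = step,
    chrom_len = chrom_len, estimator = estimator
  )
  scan[, c("chrom", "start", "end", "n_snps", "fst")]
}

#' Sliding-window scan: FST, per-population diversity, diversity ratio
#'
#' The full per-window table feeding [call_sweeps()]. The diversity ratio
#' is `pi_p1 / pi_p2` (numerator population first): values well below 1
#' mean diversity depletion in `pop1`, values well above 1 depletion in
#' `pop2`.
#'
#' @inheritParams window_fst
#' @param pop2 Second population label, or `NULL` to compute diversity for
#'   `pop1` only (used by [window_pi()]).
#' @return `data.frame(chrom, start, end, n_snps, fst, pi_p1, pi_p2,
#'   pi_ratio)` with the population labels attached as attribute
#'   `populations`.
#' @export
sweep_scan <- function(g, pop1, pop2, window = 5e6, step = 1e5,
                       chrom_len = NULL, estimator = c("nei", "wc")) {
  stopifnot(inherits(g, "genotype_matrix"))
  estimator <- match.arg(estimator)
  if (window < step) stopf("window must be >= step")
  if (!is.null(pop2) && identical(pop1, pop2)) {
    stopf("pop1 and pop2 must differ")
  }
  v <- g$variants
  check_variants_sorted(v)
  lens <- resolve_chrom_len(g, chrom_len)

  two_pop <- !is.null(pop2)
  if (two_pop) {
    st <- snp_stats(g, pop1, pop2)
    wc <- if (estimator == "wc") wc_components(st) else NULL
  } else {
    i1 <- pop_index(g, pop1)
    m <- g$calls[i1, , drop = FALSE]
    ncal <- 2 * colSums(!is.na(m))
    p <- colSums(m, na.rm = TRUE) / ncal
    st <- list(
      pi1 = ifelse(ncal >= 2, ncal / (ncal - 1) * 2 * p * (1 - p), NA_real_),
      pi2 = NA_real_, hs = NA_real_, ht = NA_real_, fst_ok = FALSE
    )
  }

  out <- list()
  for (ch in names(lens)) {
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    grid <- window_grid(lens[[ch]], window, step)
    n_in <- window_sums(pos, rep(1, length(idx)), rep(TRUE, length(idx)),
      grid
    )$n
    pi1 <- window_sums(pos, st$pi1[idx], !is.na(st$pi1[idx]), grid)$sum /
      (grid$end - grid$start + 1)
    res <- data.frame(
      chrom = ch, start = grid$start, end = grid$end,
      n_snps = n_in, pi_p1 = pi1
    )
    if (two_pop) {
      pi2 <- window_sums(pos, st$pi2[idx], !is.na(st$pi2[idx]), grid)$sum /
        (grid$end - grid$start + 1)
      if (estimator == "nei") {
        shs <- window_sums(pos, st$hs[idx], st$fst_ok[idx], grid)$sum
        sht <- window_sums(pos, st$ht[idx], st$fst_ok[idx], grid)$sum
        res$fst <- ifelse(sht > 0, (sht - shs) / sht, NA_real_)
      } else {
        sa <- window_sums(pos, wc$a[idx], wc$ok[idx], grid)$sum
        sd <- window_sums(pos, wc$denom[idx], wc$ok[idx], grid)$sum
        res$fst <- ifelse(sd > 0, sa / sd, NA_real_)
      }
      res$pi_p2 <- pi2
      res$pi_ratio <- ifelse(pi2 > 0, pi1 / pi2, NA_real_)
    }
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (two_pop) {
    res <- res[, c(
      "chrom", "start", "end", "n_snps", "fst", "pi_p1", "pi_p2", "pi_ratio"
    )]
    attr(res, "populations") <- c(pop1, pop2)
  }
  res
}

#' Min-max normalization to \[0, 1\]
#'
#' `y_i = (x_i - min x) / (max x - min x)`; rank-preserving, used for
#' display. Thresholding on scaled and unscaled values selects identical
#' window sets because the transform is strictly monotone.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Scaled vector in \[0, 1\] (`NA` preserved).
#' @export
minmax_scale <- function(values) {
  fin <- values[is.finite(values)]
  if (length(unique(fin)) < 2) {
    stopf("min-max scaling undefined: fewer than 2 distinct values")
  }
  (values - min(fin)) / (max(fin) - min(fin))
}

# nearest-rank empirical quantile (inclusive selection at the threshold)
nearest_rank <- function(x, q) {
  s <- sort(x)
  s[max(1L, ceiling(q * length(s)))]
}

#' Call selective-sweep windows from a scan table
#'
#' Windows passing the SNP-count filter define the empirical thresholds:
#' the 99th percentile of FST and the 99th/1st percentiles of the diversity
#' ratio (nearest-rank, inclusive). A window is called swept in the
#' numerator population (`pop1`) when its FST reaches the top threshold AND
#' its ratio is at or below the bottom threshold (diversity depleted in the
#' numerator); swept in `pop2` when FST reaches the top threshold AND the
#' ratio is at or above the top threshold. Overlapping or book-ended
#' selected windows are merged per direction into regions.
#'
#' @param windows A [sweep_scan()] table (two-population form).
#' @param top_frac Tail fraction for the thresholds (default 0.01).
#' @param min_snps Windows with fewer SNPs are excluded from threshold
#'   computation and from selection (default 2).
#' @param combine `"intersect"` (FST and ratio criteria must both hold; the
#'   default) or `"union"` (either suffices).
#' @return A `sweep_callset`: list with `thresholds`, the augmented
#'   `windows` table (eligibility, scaled statistics, per-direction
#'   selection flags), merged `regions`
#'   (`data.frame(chrom, start, end, population, n_windows)`), and the
#'   population labels.
#' @export
call_sweeps <- function(windows, top_frac = 0.01, min_snps = 2,
                        combine = c("intersect", "union")) {
  combine <- match.arg(combine)
  pops <- attr(windows, "populations") %||% c("pop1", "pop2")
  w <- as.data.frame(windows)
  if (!all(c("fst", "pi_ratio") %in% names(w))) {
    stopf("windows must carry fst and pi_ratio (two-population scan)")
  }
  w$eligible <- w$n_snps >= min_snps &
    is.finite(w$fst) & is.finite(w$pi_ratio)
  m <- sum(w$eligible)
  if (m < 100) {
    warnf(
      "only %d eligible windows; %g%% quantile thresholds are coarse",
      m, 100 * top_frac
    )
  }
  fst_e <- w$fst[w$eligible]
  ratio_e <- w$pi_ratio[w$eligible]
  degenerate <- length(unique(fst_e)) < 2 || length(unique(ratio_e)) < 2
  if (degenerate) {
    warnf("degenerate statistic distribution; no windows called")
    thr <- list(fst_q99 = NA_real_, ratio_q99 = NA_real_,
      ratio_q01 = NA_real_)
    w$fst_scaled <- NA_real_
    w$ratio_scaled <- NA_real_
    sel1 <- sel2 <- rep(FALSE, nrow(w))
  } else {
    thr <- list(
      fst_q99 = nearest_rank(fst_e, 1 - top_frac),
      ratio_q99 = nearest_rank(ratio_e, 1 - top_frac),
      ratio_q01 = nearest_rank(ratio_e, top_frac)
    )
    w$fst_scaled <- NA_real_
    w$fst_scaled[w$eligible] <- minmax_scale(fst_e)
    w$ratio_scaled <- NA_real_
    w$ratio_scaled[w$eligible] <- minmax_scale(ratio_e)
    high_fst <- w$eligible & w$fst >= thr$fst_q99
    low_ratio <- w$eligible & w$pi_ratio <= thr$ratio_q01
    high_ratio <- w$eligible & w$pi_ratio >= thr$ratio_q99
    if (combine == "intersect") {
      sel1 <- high_fst & low_ratio
      sel2 <- high_fst & high_ratio
    } else {
      sel1 <- high_fst | low_ratio
      sel2 <- high_fst | high_ratio
    }
  }
  w[[paste0("selected_", pops[1])]] <- sel1
  w[[paste0("selected_", pops[2])]] <- sel2
  regions <- rbind(
    merge_windows(w[sel1, , drop = FALSE], pops[1]),
    merge_windows(w[sel2, , drop = FALSE], pops[2])
  )
  structure(
    list(
      thresholds = c(thr, list(top_frac = top_frac, min_snps = min_snps,
        combine = combine)),
      windows = w,
      regions = regions,
      populations = pops
    ),
    class = "sweep_callset"
  )
}

# merge overlapping/book-ended selected windows into regions
merge_windows <- function(w, population) {
  if (!nrow(w)) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      population = character(), n_windows = integer(),
      stringsAsFactors = FALSE
    ))
  }
  w <- w[order(w$chrom, w$start), ]
  out <- list()
  cur <- w[1, c("chrom", "start", "end")]
  cur$n <- 1L
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && w$start[i] <= cur$end + 1) {
      cur$end <- max(cur$end, w$end[i])
      cur$n <- cur$n + 1L
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- w[i, c("chrom", "start", "end")]
      cur$n <- 1L
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  data.frame(
    chrom = res$chrom, start = res$start, end = res$end,
    population = population, n_windows = res$n,
    stringsAsFactors = FALSE
  )
}

#' @export
print.sweep_callset <- function(x, ...) {
  cat("sweep_callset\n")
  cat(sprintf(
    "  thresholds: FST >= %.4g; ratio <= %.4g (%s) / >= %.4g (%s)\n",
    x$thresholds$fst_q99, x$thresholds$ratio_q01, x$populations[1],
    x$thresholds$ratio_q99, x$populations[2]
  ))
  for (p in x$populations) {
    r <- x$regions[x$regions$population == p, ]
    cat(sprintf(
      "  %s: %d selected window(s) in %d region(s)\n",
      p, sum(x$windows[[paste0("selected_", p)]]), nrow(r)
    ))
  }
  invisible(x)
}

#' Candidate SNPs inside called sweep regions
#'
#' @param callset A [call_sweeps()] result.
#' @param variants Variant table (`data.frame` with `chrom`, `pos`, `vid`)
#'   or a [genotype_matrix()].
#' @return `data.frame(vid, chrom, pos, direction)`; a SNP appears once per
#'   direction whose regions contain it.
#' @export
candidate_snps <- function(callset, variants) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$variants
  out <- list()
  for (p in callset$populations) {
    reg <- callset$regions[callset$regions$population == p, , drop = FALSE]
    hit <- rep(FALSE, nrow(variants))
    for (k in seq_len(nrow(reg))) {
      hit <- hit | (variants$chrom == reg$chrom[k] &
        variants$pos >= reg$start[k] & variants$pos <= reg$end[k])
    }
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        vid = variants$vid[hit], chrom = variants$chrom[hit],
        pos = variants$pos[hit], direction = p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      vid = character(), chrom = character(), pos = integer(),
      direction = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Region-level recovery of planted sweeps
#'
#' Compares called regions against a truth set: a called region is a true
#' positive when it overlaps (>= 1 bp) a truth interval planted in the same
#' population; a truth interval is recovered when any same-population
#' called region overlaps it. Precision and recall are pooled over both
#' directions.
#'
#' @param callset A [call_sweeps()] result.
#' @param truth `data.frame(chrom, start, end, swept_pop)` of planted
#'   sweeps (e.g. from [simulate_genotypes()] or [read_truth_bed()]).
#' @return List with `precision`, `recall`, `n_regions`, `n_truth`.
#' @export
sweep_recovery <- function(callset, truth) {
  reg <- callset$regions
  overlaps <- function(a_chrom, a_start, a_end, pop, tr) {
    any(tr$chrom == a_chrom & tr$swept_pop == pop &
      tr$start <= a_end & tr$end >= a_start)
  }
  tp <- 0L
  for (i in seq_len(nrow(reg))) {
    if (overlaps(
      reg$chrom[i], reg$start[i], reg$end[i], reg$population[i], truth
    )) {
      tp <- tp + 1L
    }
  }
  recovered <- 0L
  for (i in seq_len(nrow(truth))) {
    r <- reg[reg$population == truth$swept_pop[i] &
      reg$chrom == truth$chrom[i] &
      reg$start <= truth$end[i] & reg$end >= truth$start[i], ]
    if (nrow(r)) recovered <- recovered + 1L
  }
  list(
    precision = if (nrow(reg)) tp / nrow(reg) else NA_real_,
    recall = if (nrow(truth)) recovered / nrow(truth) else NA_real_,
    n_regions = nrow(reg),
    n_truth = nrow(truth)
  )
}

#' Write called sweep regions as BED files (one per direction)
#' @param callset A [call_sweeps()] result.
#' @param prefix Output prefix; files are `<prefix>_<population>.bed`.
#' @return Invisible character vector of paths.
#' @export
write_region_bed <- function(callset, prefix) {
  paths <- character(0)
  for (p in callset$populations) {
    reg <- callset$regions[callset$regions$population == p, , drop = FALSE]
    path <- sprintf("%s_%s.bed", prefix, p)
    write_truth_bed(
      data.frame(
        chrom = reg$chrom, start = reg$start, end = reg$end,
        swept_pop = reg$population, stringsAsFactors = FALSE
      ),
      path
    )
    paths <- c(paths, path)
  }
  invisible(paths)
}
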