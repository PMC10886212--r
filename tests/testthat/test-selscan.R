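# Windowed diversity, FST, min-max scaling, sweep calling.

test_that("single-SNP window diversity matches the unbiased formula", {
  # one SNP, 2 samples (4 called alleles), alt frequency 0.5, 1 kb window:
  # pi = (4/3) * 2 * 0.5 * 0.5 / 1000
  g <- gm(cbind(c(0L, 2L)), pos = c(100L), populations = c("x", "x"))
  res <- window_pi(g, "x", window = 1000, step = 1000, chrom_len = 1000)
  expect_equal(res$pi, (4 / 3) * 0.5 / 1000, tolerance = 1e-12)
  expect_error(window_pi(g, "nope", window = 1000, step = 1000), "unknown")
})

test_that("window diversity equals the haplotype mismatch-fraction oracle", {
  set.seed(19)
  n <- 5
  m <- 40
  hap <- matrix(rbinom(2 * n * m, 1, 0.4), nrow = 2 * n)
  calls <- hap[seq(1, 2 * n, by = 2), ] + hap[seq(2, 2 * n, by = 2), ]
  pos <- sort(sample.int(5000, m))
  g <- gm(calls, pos = pos, populations = rep("x", n))
  res <- window_pi(g, "x", window = 1000, step = 500, chrom_len = 5000)
  want <- oracle_window_pi_haplotypes(hap, pos, 1000, 500, 5000)
  expect_equal(res$pi, want, tolerance = 1e-9)
})

test_that("monomorphic windows have zero diversity", {
  g <- gm(cbind(c(0L, 0L), c(2L, 2L)), pos = c(100L, 200L),
    populations = c("x", "x")
  )
  res <- window_pi(g, "x", window = 1000, step = 1000, chrom_len = 1000)
  expect_equal(res$pi, 0)
})

test_that("windowed FST reproduces the closed-form single-SNP cases", {
  # equal frequencies -> 0
  d <- c(0L, 1L, 2L, 1L, 0L)
  g <- gm(cbind(c(d, d)), pos = 100L, populations = rep(c("a", "b"), each = 5))
  w <- window_fst(g, "a", "b", window = 1000, step = 1000, chrom_len = 1000)
  expect_equal(w$fst, 0, tolerance = 1e-12)

  # opposite fixation -> 1
  g2 <- gm(cbind(rep(c(2L, 0L), each = 5)), pos = 100L,
    populations = rep(c("a", "b"), each = 5)
  )
  w2 <- window_fst(g2, "a", "b", window = 1000, step = 1000, chrom_len = 1000)
  expect_equal(w2$fst, 1, tolerance = 1e-12)

  # p1 = 0.9, p2 = 0.1 -> Hs = 0.18, Ht = 0.5, FST = 0.64
  d1 <- c(2L, 2L, 2L, 2L, 1L) # alt frequency 9/10
  d2 <- c(0L, 0L, 0L, 0L, 1L)
  g3 <- gm(cbind(c(d1, d2)), pos = 100L,
    populations = rep(c("a", "b"), each = 5)
  )
  w3 <- window_fst(g3, "a", "b", window = 1000, step = 1000, chrom_len = 1000)
  expect_equal(w3$fst, 0.64, tolerance = 1e-12)
})

test_that("windowed FST agrees with the brute-force oracle", {
  g <- random_gm(12, 80, miss = 0.1, seed = 23,
    populations = rep(c("a", "b"), 6)
  )
  # spread positions over 8 kb
  g$variants$pos <- sort(sample.int(8000, 80))
  g <- genotype_matrix(g$calls, g$variants, g$samples)
  w <- window_fst(g, "a", "b", window = 2000, step = 500, chrom_len = 8000)
  want <- oracle_window_fst(g, "a", "b", 2000, 500, 8000)
  expect_equal(nrow(w), nrow(want))
  ok <- !is.na(want$fst)
  expect_equal(w$fst[ok], want$fst[ok], tolerance = 1e-9)
})

test_that("window bookkeeping matches floor((L - window)/step) + 1", {
  for (L in c(1e6, 5.05e6, 2.34e6)) {
    for (win in c(1e6, 5e5)) {
      step <- 1e5
      g <- gm(cbind(c(0L, 1L, 2L, 1L)), pos = 100L)
      w <- window_pi(g, "p1", window = win, step = step, chrom_len = L)
      expect_equal(nrow(w), floor((L - win) / step) + 1)
    }
  }
  # each SNP lands in exactly the windows covering its position
  set.seed(44)
  pos <- sort(sample.int(3e4, 25))
  g <- gm(matrix(sample(0:2, 100, replace = TRUE), nrow = 4), pos = pos)
  w <- window_pi(g, "p1", window = 5e3, step = 1e3, chrom_len = 3e4)
  brute <- vapply(seq_len(nrow(w)), function(i) {
    sum(pos >= w$start[i] & pos <= w$end[i])
  }, 0L)
  expect_equal(w$n_snps, brute)
})

test_that("Weir-Cockerham estimator is unbiased for the drift parameter", {
  # closed-form check at known frequencies is impractical; use the
  # simulator's design property: E[theta_hat] ~ F while the
  # heterozygosity form targets F/(2-F) plus sampling terms
  sim <- simulate_genotypes(sim_params(
    n_pop1 = 50, n_pop2 = 50, n_chrom = 2, chrom_len = 5e6,
    snp_density = 1e-3, missing_rate = 0.02,
    sweeps = data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      swept_pop = character(), stringsAsFactors = FALSE
    ),
    seed = 61
  ))
  g <- sim$genotypes
  wc <- window_fst(g, "highland", "lowland",
    window = 5e6, step = 5e6, chrom_len = 5e6, estimator = "wc"
  )
  nei <- window_fst(g, "highland", "lowland",
    window = 5e6, step = 5e6, chrom_len = 5e6, estimator = "nei"
  )
  f <- 0.03
  expect_lt(abs(mean(wc$fst) - f) / f, 0.3)
  # heterozygosity form: F/(2-F) with binomial sampling corrections,
  # total alleles per population m = 100
  m <- 100
  nei_expect <- (f + (1 - f) / m) /
    (2 * (1 - f / 2 - (1 - f) / (2 * m)))
  expect_lt(abs(mean(nei$fst) - nei_expect) / nei_expect, 0.3)
})

test_that("min-max scaling matches its formula and preserves ranks", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(2)
  x <- rnorm(50)
  y <- minmax_scale(x)
  expect_equal(y[which.min(x)], 0)
  expect_equal(y[which.max(x)], 1)
  expect_equal(order(y), order(x))
  expect_error(minmax_scale(rep(3, 5)), "distinct")
})

synthetic_windows <- function(fst, ratio, n_snps = 10L) {
  n <- length(fst)
  w <- data.frame(
    chrom = "1",
    start = (seq_len(n) - 1) * 1e5 + 1,
    end = (seq_len(n) - 1) * 1e5 + 1e6,
    n_snps = n_snps,
    fst = fst,
    pi_p1 = 1e-4, pi_p2 = 1e-4,
    pi_ratio = ratio
  )
  attr(w, "populations") <- c("p1", "p2")
  w
}

test_that("a single doubly-extreme window is the sole call", {
  set.seed(71)
  fst <- seq(0.01, 0.2, length.out = 100)
  ratio <- stats::runif(100, 0.8, 1.2)
  # non-adjacent window (index 50) carries the extreme signal
  fst[50] <- 0.9
  ratio[50] <- 0.01
  w <- synthetic_windows(fst, ratio)
  calls <- call_sweeps(w)
  expect_equal(which(calls$windows$selected_p1), 50L)
  expect_equal(sum(calls$windows$selected_p2), 0L)
  expect_equal(nrow(calls$regions), 1L)
  expect_equal(calls$regions$population, "p1")
})

test_that("degenerate statistic distributions yield an empty call set", {
  w <- synthetic_windows(rep(0.1, 120), rep(1, 120))
  expect_warning(calls <- call_sweeps(w), "degenerate")
  expect_equal(nrow(calls$regions), 0L)
})

test_that("few windows triggers a quantile-resolution warning", {
  w <- synthetic_windows(seq(0.01, 0.2, length.out = 50), runif(50))
  expect_warning(call_sweeps(w), "eligible windows")
})

test_that("windows below min_snps are excluded from quantiles and calls", {
  fst <- seq(0.01, 0.2, length.out = 120)
  ratio <- seq(2, 0.5, length.out = 120)
  w <- synthetic_windows(fst, ratio)
  w$n_snps[120] <- 1L # the top-FST window loses eligibility
  calls <- call_sweeps(w, min_snps = 2)
  expect_false(calls$windows$selected_p1[120])
  expect_equal(
    calls$thresholds$fst_q99,
    sort(fst[-120])[ceiling(0.99 * 119)]
  )
})

test_that("selection from scaled statistics equals selection from raw", {
  set.seed(83)
  fst <- c(stats::rbeta(300, 2, 30), stats::rbeta(12, 10, 5))
  ratio <- c(stats::rlnorm(300, 0, 0.3), stats::rlnorm(12, -2, 0.4))
  w <- synthetic_windows(fst, ratio)
  calls_raw <- call_sweeps(w)
  w_scaled <- w
  w_scaled$fst <- minmax_scale(w$fst)
  w_scaled$pi_ratio <- minmax_scale(w$pi_ratio)
  calls_scaled <- call_sweeps(w_scaled)
  expect_identical(
    calls_raw$windows$selected_p1, calls_scaled$windows$selected_p1
  )
  expect_identical(
    calls_raw$windows$selected_p2, calls_scaled$windows$selected_p2
  )
})

test_that("adjacent selected windows merge and candidate SNPs lie inside", {
  fst <- seq(0.018, 0.022, length.out = 300)
  ratio <- seq(1.1, 0.9, length.out = 300)
  # three spatially overlapping windows carry the signal; top 1% of 300
  # windows is exactly 3 selection slots per criterion
  fst[c(40, 41, 42)] <- c(0.5, 0.55, 0.6)
  ratio[c(40, 41, 42)] <- c(0.010, 0.012, 0.011)
  w <- synthetic_windows(fst, ratio)
  calls <- call_sweeps(w)
  r1 <- calls$regions[calls$regions$population == "p1", ]
  expect_equal(nrow(r1), 1L) # three overlapping windows merged
  expect_equal(r1$n_windows, 3L)
  expect_equal(r1$start, w$start[40])
  expect_equal(r1$end, w$end[42])
  expect_equal(sum(calls$windows$selected_p2), 0L)

  variants <- data.frame(
    chrom = "1",
    pos = c(w$start[41], w$end[42], w$start[120] + 5, 1e7 + 5e6),
    vid = paste0("m", 1:4), stringsAsFactors = FALSE
  )
  snps <- candidate_snps(calls, variants)
  expect_setequal(snps$vid[snps$direction == "p1"], c("m1", "m2"))
  expect_false("m3" %in% snps$vid)
  # every candidate SNP lies inside a selected region of its direction
  for (r in seq_len(nrow(snps))) {
    reg <- calls$regions[calls$regions$population == snps$direction[r], ]
    expect_true(any(
      reg$chrom == snps$chrom[r] & reg$start <= snps$pos[r] &
        reg$end >= snps$pos[r]
    ))
  }
})

test_that("planted sweeps are recovered with high precision and recall", {
  sim <- study_sim(seed = 301)
  calls <- call_sweeps(study_scan(sim$genotypes))
  rec <- sweep_recovery(calls, sim$truth)
  expect_gte(rec$precision, 0.7)
  expect_gte(rec$recall, 0.7)
})
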