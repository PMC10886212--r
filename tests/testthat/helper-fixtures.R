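# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately re-derive each statistic from its definition with
# plain loops, independent of the package's vectorized implementations.

# quick genotype_matrix: calls is samples x variants
gm <- function(calls, chrom = "1", pos = NULL, populations = NULL) {
  calls <- as.matrix(calls)
  nv <- ncol(calls)
  ns <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  chrom <- rep_len(chrom, nv)
  if (is.null(populations)) {
    populations <- rep(c("p1", "p2"), length.out = ns)
  }
  genotype_matrix(
    calls,
    data.frame(
      chrom = chrom, pos = pos,
      vid = paste0("v", seq_len(nv)), ref = "A", alt = "G",
      stringsAsFactors = FALSE
    ),
    data.frame(
      sample_id = sprintf("s%02d", seq_len(ns)),
      population = populations, stringsAsFactors = FALSE
    )
  )
}

# random genotype matrix with optional missingness
random_gm <- function(ns, nv, miss = 0, seed = 1, chrom = "1",
                      populations = NULL) {
  set.seed(seed)
  calls <- matrix(sample(0:2, ns * nv, replace = TRUE), nrow = ns)
  if (miss > 0) calls[runif(ns * nv) < miss] <- NA
  gm(calls, chrom = chrom, populations = populations)
}

# enumeration oracle for the exact HWE test: probabilities of every
# heterozygote count compatible with the allele totals, via choose()
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n - n_A
  if (n_A == 0 || n_a == 0) {
    return(1)
  }
  hs <- seq(min(n_A, n_a) %% 2, min(n_A, n_a), by = 2)
  prob <- vapply(hs, function(h) {
    choose(n, h) * choose(n - h, (n_A - h) / 2) * 2^h / choose(2 * n, n_A)
  }, 0)
  obs <- prob[hs == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# brute-force IBS distance: per-pair loop over jointly called variants
oracle_ibs <- function(g) {
  m <- g$calls
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      shared <- sum(2 - abs(m[i, ok] - m[j, ok]))
      d[i, j] <- 1 - shared / (2 * sum(ok))
    }
  }
  dimnames(d) <- list(g$samples$sample_id, g$samples$sample_id)
  d
}

# upper-tail hypergeometric probability by direct summation
oracle_hyper <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# per-window Hs/Ht sums by direct per-SNP loops and interval scans
oracle_window_fst <- function(g, pop1, pop2, window, step, chrom_len) {
  i1 <- which(g$samples$population == pop1)
  i2 <- which(g$samples$population == pop2)
  v <- g$variants
  out <- list()
  for (ch in unique(v$chrom)) {
    starts <- seq(1, chrom_len - window + 1, by = step)
    for (s in starts) {
      e <- s + window - 1
      idx <- which(v$chrom == ch & v$pos >= s & v$pos <= e)
      hs_sum <- ht_sum <- 0
      for (j in idx) {
        d1 <- g$calls[i1, j]
        d2 <- g$calls[i2, j]
        d1 <- d1[!is.na(d1)]
        d2 <- d2[!is.na(d2)]
        if (length(d1) < 1 || length(d2) < 1) next
        if (2 * length(d1) < 2 || 2 * length(d2) < 2) next
        p1 <- sum(d1) / (2 * length(d1))
        p2 <- sum(d2) / (2 * length(d2))
        hs_sum <- hs_sum + (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
        pb <- (p1 + p2) / 2
        ht_sum <- ht_sum + 2 * pb * (1 - pb)
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = s, end = e,
        fst = if (ht_sum > 0) (ht_sum - hs_sum) / ht_sum else NA_real_
      )
    }
  }
  do.call(rbind, out)
}

# windowed diversity from explicit haplotypes: average per-site mismatch
# fraction over all chromosome pairs, divided by window length
oracle_window_pi_haplotypes <- function(hap, pos, window, step, chrom_len) {
  nc <- nrow(hap) # haplotypes (2 per sample)
  starts <- seq(1, chrom_len - window + 1, by = step)
  vapply(starts, function(s) {
    idx <- which(pos >= s & pos <= s + window - 1)
    tot <- 0
    for (j in idx) {
      mism <- 0
      for (a in seq_len(nc - 1)) {
        for (b in (a + 1):nc) {
          mism <- mism + (hap[a, j] != hap[b, j])
        }
      }
      tot <- tot + mism / choose(nc, 2)
    }
    tot / window
  }, 0)
}

# distance matrix of path lengths for a 4-taxon tree
# ((t1:b1, t2:b2):b0, t3:b3, t4:b4) with central split t1t2 | t3t4
additive_matrix_4taxa <- function(b1, b2, b0, b3, b4,
                                  labels = c("t1", "t2", "t3", "t4")) {
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d["t1", "t2"] <- d["t2", "t1"] <- b1 + b2
  d["t1", "t3"] <- d["t3", "t1"] <- b1 + b0 + b3
  d["t1", "t4"] <- d["t4", "t1"] <- b1 + b0 + b4
  d["t2", "t3"] <- d["t3", "t2"] <- b2 + b0 + b3
  d["t2", "t4"] <- d["t4", "t2"] <- b2 + b0 + b4
  d["t3", "t4"] <- d["t4", "t3"] <- b3 + b4
  d
}

# 50 samples; one variant planted to fail each QC stage, three clean ones
planted_qc_fixture <- function() {
  n <- 50
  good <- function(seed) {
    set.seed(seed)
    sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  }
  v_cr <- good(1)
  v_cr[1:10] <- NA # call rate 0.8 < 0.9
  v_x <- good(2) # fine except chromosome X
  v_maf <- c(rep(0L, n - 1), 1L) # MAF = 1/100 < 0.05
  v_hwe <- rep(1L, n) # all heterozygous: exact p ~ 1e-14
  calls <- cbind(v_cr, good(3), v_x, v_maf, good(4), v_hwe, good(5))
  gm(calls,
    chrom = c("1", "1", "X", "2", "2", "3", "3"),
    pos = c(100L, 200L, 100L, 100L, 200L, 100L, 200L)
  )
}

# write the three-gene fixture as GFF3 and as BED12; returns paths
write_gene_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("genes")
    dir.create(dir)
  }
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "genes.bed")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=geneA;Name=geneA",
    "1\ttest\texon\t1001\t2000\t.\t+\t.\tID=geneA.e1;Parent=geneA",
    "1\ttest\tgene\t5001\t6000\t.\t-\t.\tID=geneB;Name=geneB",
    "1\ttest\texon\t5001\t5200\t.\t-\t.\tID=geneB.e1;Parent=geneB",
    "1\ttest\texon\t5801\t6000\t.\t-\t.\tID=geneB.e2;Parent=geneB",
    "2\ttest\tgene\t10001\t12000\t.\t+\t.\tID=geneC;Name=geneC",
    "2\ttest\texon\t10001\t12000\t.\t+\t.\tID=geneC.e1;Parent=geneC"
  ), gff)
  writeLines(c(
    paste0("1\t1000\t2000\tgeneA\t0\t+\t1000\t2000\t0\t1\t1000\t0"),
    paste0("1\t5000\t6000\tgeneB\t0\t-\t5000\t6000\t0\t2\t200,200\t0,800"),
    paste0("2\t10000\t12000\tgeneC\t0\t+\t10000\t12000\t0\t1\t2000\t0")
  ), bed)
  list(gff = gff, bed = bed)
}

write_gmt_fixture <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, ""), path)
  path
}

# study-condition simulation shared by recovery tests and docs
study_sim <- function(seed) {
  simulate_genotypes(sim_params(seed = seed))
}

study_scan <- function(g) {
  sweep_scan(g, "highland", "lowland",
    window = 1e6, step = 1e5, chrom_len = 40e6
  )
}
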