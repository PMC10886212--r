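# SNP quality control: exact Hardy-Weinberg test and the four-stage filter.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum of the conditional probabilities of all heterozygote
#' counts whose probability does not exceed that of the observed count
#' (the SNP-wise exact test of Wigginton, Cutler and Abecasis).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, not all zero).
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(0, 100, 0) # extreme heterozygote excess
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stopf("all genotype counts are zero")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0L || n_a == 0L) {
    return(1) # monomorphic: single attainable configuration
  }
  rare <- min(n_A, n_a)
  # heterozygote counts compatible with the allele totals share the parity
  # of the rare-allele count
  h <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- lfactorial(n) -
    lfactorial((n_A - h) / 2) - lfactorial(h) - lfactorial((n_a - h) / 2) +
    h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2L * n)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_Aa, h)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# per-variant genotype counts over a sample subset
genotype_counts <- function(g, samples = NULL) {
  m <- if (is.null(samples)) g$calls else g$calls[samples, , drop = FALSE]
  cbind(
    n_AA = colSums(m == 0L, na.rm = TRUE),
    n_Aa = colSums(m == 1L, na.rm = TRUE),
    n_aa = colSums(m == 2L, na.rm = TRUE)
  )
}

# vector of HWE p-values across variants
hwe_pvalues <- function(g, samples = NULL) {
  cnt <- genotype_counts(g, samples)
  apply(cnt, 1L, function(x) {
    if (sum(x) == 0) NA_real_ else hwe_exact_test(x[1], x[2], x[3])
  })
}

#' Variant quality-control filter
#'
#' Applies the chip-QC filters in a fixed order: call rate, autosome
#' membership, minor allele frequency, exact Hardy-Weinberg test. MAF and
#' (by default) the HWE test are computed over all samples pooled; the
#' per-population HWE option takes the minimum p-value across populations,
#' which avoids the heterozygote-deficit inflation that pooling two diverged
#' populations induces (Wahlund effect).
#'
#' @param g A [genotype_matrix()].
#' @param callrate_min Minimum fraction of called samples per variant.
#' @param maf_min Minimum minor-allele frequency (pooled).
#' @param hwe_p_min Variants with exact HWE p-value below this are removed.
#' @param autosomes Character set of chromosome names to keep.
#' @param hwe_by_population If `TRUE`, test HWE within each population and
#'   filter on the minimum p-value instead of the pooled test.
#' @return A list with `genotypes` (the filtered [genotype_matrix()], variant
#'   order preserved) and `report` (a `qc_report` with per-stage removal
#'   counts and the thresholds used).
#' @export
qc_filter <- function(g, callrate_min = 0.90, maf_min = 0.05,
                      hwe_p_min = 1e-6,
                      autosomes = as.character(1:18),
                      hwe_by_population = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!ncol(g$calls)) stopf("empty genotype matrix")
  n_input <- ncol(g$calls)

  callrate <- colMeans(!is.na(g$calls))
  keep <- callrate >= callrate_min
  n_callrate <- sum(!keep)
  g <- subset_genotypes(g, variants = which(keep))

  keep <- g$variants$chrom %in% autosomes
  n_auto <- sum(!keep)
  g <- subset_genotypes(g, variants = which(keep))

  keep <- !is.na(maf(g)) & maf(g) >= maf_min
  n_maf <- sum(!keep)
  g <- subset_genotypes(g, variants = which(keep))

  if (ncol(g$calls)) {
    if (hwe_by_population) {
      p <- do.call(pmin, c(
        lapply(pop_labels(g), function(pp) hwe_pvalues(g, pop_index(g, pp))),
        list(na.rm = TRUE)
      ))
    } else {
      p <- hwe_pvalues(g)
    }
    keep <- !is.na(p) & p >= hwe_p_min
  } else {
    keep <- logical(0)
  }
  n_hwe <- sum(!keep)
  g <- subset_genotypes(g, variants = which(keep))

  report <- structure(
    list(
      n_input = n_input,
      n_removed_callrate = n_callrate,
      n_removed_nonautosomal = n_auto,
      n_removed_maf = n_maf,
      n_removed_hwe = n_hwe,
      n_retained = ncol(g$calls),
      thresholds = list(
        callrate_min = callrate_min, maf_min = maf_min,
        hwe_p_min = hwe_p_min, autosomes = autosomes,
        hwe_by_population = hwe_by_population
      )
    ),
    class = "qc_report"
  )
  stopifnot(
    report$n_input - report$n_removed_callrate -
      report$n_removed_nonautosomal - report$n_removed_maf -
      report$n_removed_hwe == report$n_retained
  )
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat(sprintf("  input variants:        %d\n", x$n_input))
  cat(sprintf(
    "  removed, call rate:    %d (< %.2f)\n",
    x$n_removed_callrate, x$thresholds$callrate_min
  ))
  cat(sprintf("  removed, non-autosome: %d\n", x$n_removed_nonautosomal))
  cat(sprintf(
    "  removed, MAF:          %d (< %.3f)\n",
    x$n_removed_maf, x$thresholds$maf_min
  ))
  cat(sprintf(
    "  removed, HWE:          %d (p < %g%s)\n",
    x$n_removed_hwe, x$thresholds$hwe_p_min,
    if (x$thresholds$hwe_by_population) ", per population" else ", pooled"
  ))
  cat(sprintf("  retained:              %d\n", x$n_retained))
  invisible(x)
}

#' Write a QC report as a two-column TSV
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c(
      "n_input", "n_removed_callrate", "n_removed_nonautosomal",
      "n_removed_maf", "n_removed_hwe", "n_retained",
      "callrate_min", "maf_min", "hwe_p_min"
    ),
    value = c(
      report$n_input, report$n_removed_callrate,
      report$n_removed_nonautosomal, report$n_removed_maf,
      report$n_removed_hwe, report$n_retained,
      report$thresholds$callrate_min, report$thresholds$maf_min,
      report$thresholds$hwe_p_min
    )
  )
  write_tsv(df, path)
}
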