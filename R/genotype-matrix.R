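#' Genotype matrix container
#'
#' The central data structure of the package: a samples x variants matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for a missing call) together
#' with a variant table and a sample table.
#'
#' @param calls Integer matrix, samples in rows, variants in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based bp),
#'   `vid`, `ref`, `alt`; one row per column of `calls`. `(chrom, pos)` must
#'   be unique and `ref != alt`.
#' @param samples `data.frame` with columns `sample_id` (unique) and
#'   `population` (non-empty label); one row per row of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `samples`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), nrow = 2),
#'   data.frame(
#'     chrom = "1", pos = c(100L, 200L), vid = c("s1", "s2"),
#'     ref = "A", alt = "G"
#'   ),
#'   data.frame(sample_id = c("a", "b"), population = c("p1", "p2"))
#' )
#' dim(g$calls)
#' @export
genotype_matrix <- function(calls, variants, samples) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("chrom", "pos", "vid", "ref", "alt")
  if (!all(need_v %in% names(variants))) {
    stopf(
      "variants table must have columns: %s",
      paste(need_v, collapse = ", ")
    )
  }
  if (!all(c("sample_id", "population") %in% names(samples))) {
    stopf("samples table must have columns sample_id, population")
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(samples) != nrow(calls) || nrow(variants) != ncol(calls)) {
    stopf(
      "calls is %d x %d but %d samples and %d variants supplied",
      nrow(calls), ncol(calls), nrow(samples), nrow(variants)
    )
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stopf("dosages must be 0, 1, 2 or NA")
  }
  if (any(variants$pos < 1L)) stopf("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stopf("ref and alt must differ")
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key)) {
    stopf("duplicated (chrom, pos): %s", key[duplicated(key)][1])
  }
  if (anyDuplicated(samples$sample_id)) stopf("duplicated sample_id")
  if (any(!nzchar(samples$population))) stopf("empty population label")
  dimnames(calls) <- list(samples$sample_id, variants$vid)
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$samples$population)
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants\n",
    nrow(x$calls), ncol(x$calls)
  ))
  cat(
    " populations:",
    paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
    "\n"
  )
  miss <- mean(is.na(x$calls))
  cat(sprintf(" missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples Optional logical/integer index or character sample ids.
#' @param variants Optional logical/integer index or character variant ids.
#' @return A `genotype_matrix` restricted to the requested rows/columns,
#'   order preserved as given by the index.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- seq_len(nrow(g$calls))
  vi <- seq_len(ncol(g$calls))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, g$samples$sample_id)
    } else {
      si[samples]
    }
    if (anyNA(si)) stopf("unknown sample in subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) {
      match(variants, g$variants$vid)
    } else {
      vi[variants]
    }
    if (anyNA(vi)) stopf("unknown variant in subset")
  }
  genotype_matrix(
    g$calls[si, vi, drop = FALSE],
    g$variants[vi, , drop = FALSE],
    g$samples[si, , drop = FALSE]
  )
}

# variants must form one contiguous block per chromosome with positions
# strictly ascending inside each block (chromosome order itself is free)
check_variants_sorted <- function(variants) {
  r <- rle(variants$chrom)
  if (anyDuplicated(r$values)) {
    stopf("variants must be sorted by (chrom, pos)")
  }
  ok <- tapply(variants$pos, factor(variants$chrom, levels = r$values),
    function(p) all(diff(p) > 0)
  )
  if (!all(ok)) stopf("variants must be sorted by (chrom, pos)")
  invisible(TRUE)
}

# row indices of one population's samples (error on unknown label)
pop_index <- function(g, population) {
  idx <- which(g$samples$population == population)
  if (!length(idx)) stopf("unknown population label: '%s'", population)
  idx
}

# the two population labels, first-seen order
pop_labels <- function(g) unique(g$samples$population)

#' Pooled alternate-allele frequency per variant
#'
#' @param g A [genotype_matrix()].
#' @param samples Optional row index restricting to a subset of samples.
#' @return Numeric vector of ALT frequencies among called alleles (`NaN`
#'   where no sample is called).
#' @export
alt_freq <- function(g, samples = NULL) {
  m <- if (is.null(samples)) g$calls else g$calls[samples, , drop = FALSE]
  colMeans(m, na.rm = TRUE) / 2
}

# minor allele frequency over all samples pooled
maf <- function(g) {
  p <- alt_freq(g)
  pmin(p, 1 - p)
}
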