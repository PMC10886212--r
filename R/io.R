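# Genotype input/output: VCF, PLINK-style .ped/.map text, popmap TSV.

#' Read a sample-to-population map
#'
#' A popmap is a headerless two-column TSV: `sample_id<TAB>population`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `sample_id`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path,
    header = FALSE, sep = "\t",
    stringsAsFactors = FALSE, col.names = c("sample_id", "population"),
    colClasses = "character"
  )
  if (anyDuplicated(pm$sample_id)) {
    stopf("duplicated sample_id in popmap: %s",
      pm$sample_id[duplicated(pm$sample_id)][1])
  }
  pm
}

#' Write a popmap TSV
#' @param samples `data.frame` with `sample_id` and `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "population")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# attach popmap populations to a vector of sample ids (error if any missing)
match_popmap <- function(sample_ids, popmap) {
  i <- match(sample_ids, popmap$sample_id)
  if (anyNA(i)) {
    stopf(
      "sample '%s' not present in popmap", sample_ids[which(is.na(i))[1]]
    )
  }
  data.frame(
    sample_id = sample_ids,
    population = popmap$population[i],
    stringsAsFactors = FALSE
  )
}

#' Read genotypes from a VCF
#'
#' Reads diploid GT calls from a plain or bgzipped VCF and converts them to
#' alternate-allele dosages (0/1/2; `./.` becomes `NA`). Multi-allelic
#' records are rejected by default.
#'
#' @param path VCF path.
#' @param popmap Path to a popmap TSV, or a `data.frame` as returned by
#'   [read_popmap()]. Every VCF sample must be present.
#' @param multiallelic `"reject"` (drop such records, with a message) or
#'   `"first_alt"` (keep the first ALT allele; genotypes carrying other ALT
#'   alleles become missing).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap, multiallelic = c("reject", "first_alt")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) stopf("VCF has no genotype columns")
  sample_ids <- colnames(gt)[-1]
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  samples <- match_popmap(sample_ids, popmap)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "reject") {
      message(sprintf("dropping %d multi-allelic record(s)", sum(multi)))
      fix <- fix[!multi, , drop = FALSE]
      gt <- gt[!multi, , drop = FALSE]
    } else {
      fix$ALT[multi] <- vapply(
        strsplit(fix$ALT[multi], ",", fixed = TRUE), `[`, "", 1L
      )
      message(sprintf(
        "keeping first ALT for %d multi-allelic record(s)", sum(multi)
      ))
    }
  }
  if (!nrow(fix)) stopf("no biallelic records in %s", path)

  fmt <- gt[, 1]
  gt_idx <- vapply(
    strsplit(fmt, ":", fixed = TRUE),
    function(f) match("GT", f), 0L
  )
  if (anyNA(gt_idx)) {
    stopf("record %d has no GT in FORMAT", which(is.na(gt_idx))[1])
  }
  body <- gt[, -1, drop = FALSE]
  # strip trailing FORMAT fields, keep the GT token
  gt_only <- matrix(
    sub(":.*$", "", body),
    nrow = nrow(body), dimnames = dimnames(body)
  )
  a1 <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1", gt_only)
  a2 <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\2", gt_only)
  bad <- a1 == gt_only & !gt_only %in% c(".", NA)
  if (any(bad, na.rm = TRUE)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stopf(
      "malformed GT '%s' at record %d (POS %s), sample %s",
      gt_only[w[1], w[2]], w[1], fix$POS[w[1]], sample_ids[w[2]]
    )
  }
  dos1 <- allele_dosage(a1)
  dos2 <- allele_dosage(a2)
  dosage <- dos1 + dos2 # NA propagates for "." and >first-ALT alleles
  calls <- t(dosage)

  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    vid = ifelse(is.na(fix$ID) | fix$ID == ".",
      paste0(fix$CHROM, "_", fix$POS), fix$ID
    ),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  genotype_matrix(calls, variants, samples)
}

# map allele index strings to per-allele ALT dosage: "0"->0, "1"->1,
# "."->NA, ">=2" (residual multi-allelic alleles) -> NA
allele_dosage <- function(a) {
  out <- matrix(NA_integer_, nrow = nrow(a), ncol = ncol(a))
  out[a == "0"] <- 0L
  out[a == "1"] <- 1L
  out
}

#' Write genotypes as a minimal VCFv4.2 file
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", g$samples$sample_id
    ), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  m <- g$calls
  txt <- matrix("./.", nrow = nrow(m), ncol = ncol(m))
  ok <- !is.na(m)
  txt[ok] <- gt_code[m[ok] + 1L]
  v <- g$variants
  lines <- paste(
    v$chrom, v$pos, v$vid, v$ref, v$alt, ".", ".", ".", "GT",
    apply(txt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from PLINK-style .ped/.map text files
#'
#' The `.ped` file carries six leading columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per variant; the
#' `.map` file carries `chrom`, `vid`, `cM`, `pos`. Allele "0" encodes a
#' missing call. Unless `ref_alleles` is given, the ALT allele of each
#' variant is defined as the minor allele over all samples (ties broken
#' lexicographically: the lexicographically greater allele becomes ALT).
#'
#' @param ped,map Paths to the `.ped` and `.map` files.
#' @param popmap Popmap path or `data.frame`; must cover every individual id.
#' @param ref_alleles Optional path to a 3-column TSV `vid ref alt` fixing
#'   allele orientation (as written by [write_plink_text()]); required for
#'   bit-exact round trips.
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped, map, popmap, ref_alleles = NULL) {
  mp <- utils::read.table(map,
    header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "vid", "cm", "pos"),
    colClasses = c("character", "character", "character", "integer")
  )
  nvar <- nrow(mp)
  fields <- utils::count.fields(ped)
  bad <- which(fields != 6L + 2L * nvar)
  if (length(bad)) {
    stopf(
      "ped record %d has %d fields, expected %d for %d map variants",
      bad[1], fields[bad[1]], 6L + 2L * nvar, nvar
    )
  }
  pd <- as.matrix(utils::read.table(ped,
    header = FALSE,
    stringsAsFactors = FALSE, colClasses = "character"
  ))
  n <- nrow(pd)
  sample_ids <- pd[, 2]
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  samples <- match_popmap(sample_ids, popmap)

  a1 <- pd[, 6L + 2L * seq_len(nvar) - 1L, drop = FALSE]
  a2 <- pd[, 6L + 2L * seq_len(nvar), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  ra <- NULL
  if (!is.null(ref_alleles)) {
    ra <- utils::read.table(ref_alleles,
      header = FALSE, stringsAsFactors = FALSE,
      col.names = c("vid", "ref", "alt"), colClasses = "character"
    )
    i <- match(mp$vid, ra$vid)
    if (anyNA(i)) stopf("variant '%s' missing from ref_alleles",
      mp$vid[which(is.na(i))[1]])
    ra <- ra[i, , drop = FALSE]
  }

  calls <- matrix(NA_integer_, nrow = n, ncol = nvar)
  ref <- alt <- character(nvar)
  for (j in seq_len(nvar)) {
    al <- c(a1[, j], a2[, j])
    obs <- sort(unique(al[!is.na(al)]))
    if (length(obs) > 2L) {
      stopf("variant '%s' has >2 alleles in ped", mp$vid[j])
    }
    if (!is.null(ra)) {
      ref[j] <- ra$ref[j]
      alt[j] <- ra$alt[j]
    } else if (length(obs) == 0L) {
      ref[j] <- "N"
      alt[j] <- "N2" # fully missing column; placeholder orientation
    } else if (length(obs) == 1L) {
      ref[j] <- obs
      alt[j] <- if (obs == "N") "N2" else "N"
    } else {
      cnt <- c(sum(al == obs[1], na.rm = TRUE), sum(al == obs[2], na.rm = TRUE))
      if (cnt[1] == cnt[2]) {
        # tie: lexicographically greater allele is ALT
        ref[j] <- obs[1]
        alt[j] <- obs[2]
      } else {
        minor <- obs[which.min(cnt)]
        ref[j] <- setdiff(obs, minor)
        alt[j] <- minor
      }
    }
    calls[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }

  variants <- data.frame(
    chrom = mp$chrom, pos = mp$pos, vid = mp$vid,
    ref = ref, alt = alt, stringsAsFactors = FALSE
  )
  genotype_matrix(calls, variants, samples)
}

#' Write genotypes as PLINK-style .ped/.map text files
#'
#' Writes `<prefix>.ped`, `<prefix>.map` and `<prefix>.ref` (the `vid ref
#' alt` orientation table accepted by [read_plink_text()] for lossless round
#' trips).
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_plink_text <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  utils::write.table(
    data.frame(v$chrom, v$vid, 0, v$pos),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    data.frame(v$vid, v$ref, v$alt),
    paste0(prefix, ".ref"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  n <- nrow(g$calls)
  nv <- ncol(g$calls)
  al <- matrix("0", nrow = n, ncol = 2L * nv)
  for (j in seq_len(nv)) {
    d <- g$calls[, j]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1L, v$alt[j], v$ref[j]))
    second <- ifelse(is.na(d), "0", ifelse(d == 2L, v$alt[j], v$ref[j]))
    al[, 2L * j - 1L] <- first
    al[, 2L * j] <- second
  }
  lead <- cbind(
    g$samples$population, g$samples$sample_id, "0", "0", "0", "-9"
  )
  utils::write.table(cbind(lead, al), paste0(prefix, ".ped"),
    sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(c(
    ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map"),
    ref = paste0(prefix, ".ref")
  ))
}
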