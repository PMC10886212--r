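# SNP annotation against gene models and hypergeometric gene-set enrichment.

#' Load gene models from GFF3 or BED12
#'
#' GFF3: rows of type `gene` become gene models (1-based inclusive
#' coordinates pass through); rows of type `exon` are attached to a gene
#' when their `gene_id` attribute or `Parent` names a gene id directly.
#' BED12: each line is one gene, its blocks become exons (0-based half-open
#' converted to 1-based inclusive).
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A `gene_models` object: list with `genes`
#'   (`data.frame(gene_id, name, chrom, start, end, strand)`, ordered by
#'   (chrom, start)) and `exons` (`data.frame(gene_id, chrom, start, end)`).
#' @export
load_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) {
      "bed"
    } else {
      "gff3"
    }
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- as.data.frame(gr)
    is_gene <- meta$type == "gene"
    if (!any(is_gene)) stopf("no 'gene' features in %s", path)
    gid <- meta$ID %||% meta$gene_id
    if (is.null(gid)) stopf("gene features need an ID attribute")
    name_col <- if (!is.null(meta$Name)) meta$Name else gid
    genes <- data.frame(
      gene_id = as.character(gid[is_gene]),
      name = as.character(ifelse(is.na(name_col[is_gene]),
        gid[is_gene], name_col[is_gene]
      )),
      chrom = as.character(meta$seqnames[is_gene]),
      start = meta$start[is_gene],
      end = meta$end[is_gene],
      strand = as.character(meta$strand[is_gene]),
      stringsAsFactors = FALSE
    )
    is_exon <- meta$type == "exon"
    exons <- if (any(is_exon)) {
      parent <- if (!is.null(meta$Parent)) {
        vapply(meta$Parent[is_exon], function(p) {
          if (length(p)) as.character(p[1]) else NA_character_
        }, "")
      } else {
        rep(NA_character_, sum(is_exon))
      }
      eg <- if (!is.null(meta$gene_id)) {
        ifelse(is.na(meta$gene_id[is_exon]), parent, meta$gene_id[is_exon])
      } else {
        parent
      }
      keep <- !is.na(eg) & eg %in% genes$gene_id
      if (any(!keep & !is.na(eg))) {
        message(sprintf(
          "skipping %d exon(s) whose parent is not a gene feature",
          sum(!keep)
        ))
      }
      data.frame(
        gene_id = eg[keep],
        chrom = as.character(meta$seqnames[is_exon][keep]),
        start = meta$start[is_exon][keep],
        end = meta$end[is_exon][keep],
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        gene_id = character(), chrom = character(),
        start = integer(), end = integer(), stringsAsFactors = FALSE
      )
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    df <- as.data.frame(gr)
    genes <- data.frame(
      gene_id = as.character(df$name),
      name = as.character(df$name),
      chrom = as.character(df$seqnames),
      start = df$start, # rtracklayer already converts to 1-based
      end = df$end,
      strand = as.character(df$strand),
      stringsAsFactors = FALSE
    )
    exons <- if (!is.null(df$blocks)) {
      bl <- df$blocks # relative IRangesList
      pieces <- lapply(seq_len(nrow(df)), function(i) {
        b <- bl[[i]]
        data.frame(
          gene_id = genes$gene_id[i],
          chrom = genes$chrom[i],
          start = genes$start[i] + IRanges::start(b) - 1L,
          end = genes$start[i] + IRanges::end(b) - 1L,
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, pieces)
    } else {
      data.frame(
        gene_id = character(), chrom = character(),
        start = integer(), end = integer(), stringsAsFactors = FALSE
      )
    }
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  o <- order(genes$chrom, genes$start)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  if (any(genes$start > genes$end)) stopf("gene with start > end")
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "gene_models: %d gene(s), %d exon record(s), %d chromosome(s)\n",
    nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))
  ))
  invisible(x)
}

# strand-aware flank intervals for a gene table
flank_intervals <- function(genes, flank, which = c("upstream", "downstream")) {
  which <- match.arg(which)
  plus <- genes$strand != "-"
  if (which == "upstream") {
    start <- ifelse(plus, genes$start - flank, genes$end + 1)
    end <- ifelse(plus, genes$start - 1, genes$end + flank)
  } else {
    start <- ifelse(plus, genes$end + 1, genes$start - flank)
    end <- ifelse(plus, genes$end + flank, genes$start - 1)
  }
  data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = pmax(1, start), end = end, stringsAsFactors = FALSE
  )
}

gr_of <- function(df) {
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end)
  )
}

#' Annotate SNPs with genomic-element categories
#'
#' Precedence: a SNP inside a gene is `exonic` if it falls in a recorded
#' exon of that gene, otherwise `intronic` (genes without exon records
#' count as intronic throughout). Otherwise, a SNP within `flank` bp of a
#' gene start (strand-aware) is `upstream`, within `flank` bp of a gene end
#' `downstream`, and `upstream/downstream` when both hold (possibly for two
#' different genes). Everything else is `intergenic`, with the nearest gene
#' on each side within `max_flank_search` recorded.
#'
#' @param variants Variant table (`chrom`, `pos`, `vid`) or a
#'   [genotype_matrix()].
#' @param models A [load_gene_models()] object.
#' @param flank Flank width in bp for upstream/downstream (default 1 kb).
#' @param max_flank_search Search limit for intergenic neighbor genes
#'   (default 1 Mb).
#' @return `data.frame(vid, chrom, pos, category, genes)` where `genes` is
#'   a semicolon-joined gene-id list (empty string when none).
#' @export
annotate_snps <- function(variants, models, flank = 1000,
                          max_flank_search = 1e6) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$variants
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  n <- nrow(variants)
  category <- rep("intergenic", n)
  gene_hits <- vector("list", n)

  snps <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, variants$pos)
  )
  ov_gene <- GenomicRanges::findOverlaps(snps, gr_of(genes))
  qi <- S4Vectors::queryHits(ov_gene)
  si <- S4Vectors::subjectHits(ov_gene)
  exonic <- rep(FALSE, n)
  if (length(qi)) {
    ex <- models$exons
    in_exon_of <- function(i, gid) {
      e <- ex[ex$gene_id == gid, , drop = FALSE]
      nrow(e) > 0 && any(
        e$chrom == variants$chrom[i] &
          e$start <= variants$pos[i] & e$end >= variants$pos[i]
      )
    }
    for (k in seq_along(qi)) {
      i <- qi[k]
      gid <- genes$gene_id[si[k]]
      gene_hits[[i]] <- c(gene_hits[[i]], gid)
      if (in_exon_of(i, gid)) exonic[i] <- TRUE
    }
    genic <- unique(qi)
    category[genic] <- ifelse(exonic[genic], "exonic", "intronic")
  }

  non_genic <- which(category == "intergenic")
  if (length(non_genic)) {
    up <- flank_intervals(genes, flank, "upstream")
    dn <- flank_intervals(genes, flank, "downstream")
    sub <- snps[non_genic]
    ov_up <- GenomicRanges::findOverlaps(sub, gr_of(up))
    ov_dn <- GenomicRanges::findOverlaps(sub, gr_of(dn))
    is_up <- rep(FALSE, length(non_genic))
    is_dn <- rep(FALSE, length(non_genic))
    for (k in seq_along(S4Vectors::queryHits(ov_up))) {
      j <- S4Vectors::queryHits(ov_up)[k]
      i <- non_genic[j]
      is_up[j] <- TRUE
      gene_hits[[i]] <- c(
        gene_hits[[i]], up$gene_id[S4Vectors::subjectHits(ov_up)[k]]
      )
    }
    for (k in seq_along(S4Vectors::queryHits(ov_dn))) {
      j <- S4Vectors::queryHits(ov_dn)[k]
      i <- non_genic[j]
      is_dn[j] <- TRUE
      gene_hits[[i]] <- c(
        gene_hits[[i]], dn$gene_id[S4Vectors::subjectHits(ov_dn)[k]]
      )
    }
    category[non_genic[is_up & is_dn]] <- "upstream/downstream"
    category[non_genic[is_up & !is_dn]] <- "upstream"
    category[non_genic[!is_up & is_dn]] <- "downstream"
  }

  inter <- which(category == "intergenic")
  for (i in inter) {
    same <- genes[genes$chrom == variants$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    left <- same[same$end < variants$pos[i], , drop = FALSE]
    right <- same[same$start > variants$pos[i], , drop = FALSE]
    nb <- character(0)
    if (nrow(left)) {
      j <- which.max(left$end)
      if (variants$pos[i] - left$end[j] <= max_flank_search) {
        nb <- c(nb, left$gene_id[j])
      }
    }
    if (nrow(right)) {
      j <- which.min(right$start)
      if (right$start[j] - variants$pos[i] <= max_flank_search) {
        nb <- c(nb, right$gene_id[j])
      }
    }
    gene_hits[[i]] <- nb
  }

  data.frame(
    vid = variants$vid, chrom = variants$chrom, pos = variants$pos,
    category = category,
    genes = vapply(
      gene_hits, function(x) paste(unique(x), collapse = ";"), ""
    ),
    stringsAsFactors = FALSE
  )
}

#' Count SNPs per genomic-element category
#'
#' @param annotated Output of [annotate_snps()].
#' @return `data.frame(category, n)` over the fixed category set; counts
#'   sum to the number of SNPs (the categories partition the SNP set).
#' @export
category_counts <- function(annotated) {
  levels <- c(
    "exonic", "intronic", "upstream", "downstream",
    "upstream/downstream", "intergenic"
  )
  tab <- table(factor(annotated$category, levels = levels))
  data.frame(category = levels, n = as.integer(tab))
}

#' Candidate genes from annotated candidate SNPs
#'
#' Deduplicated union of the gene ids attached to the SNPs, per sweep
#' direction when a `direction` column is present.
#'
#' @param annotated Output of [annotate_snps()], optionally with a
#'   `direction` column (e.g. merged from [candidate_snps()]).
#' @param include_intergenic_neighbors Keep genes recorded for intergenic
#'   SNPs (default `TRUE`, mirroring two-neighbor annotation reporting);
#'   set `FALSE` to restrict to genic and 1 kb-flank SNPs.
#' @return Named list of character vectors (one per direction), or a single
#'   character vector when no `direction` column is present.
#' @export
candidate_genes <- function(annotated, include_intergenic_neighbors = TRUE) {
  pick <- function(df) {
    if (!include_intergenic_neighbors) {
      df <- df[df$category != "intergenic", , drop = FALSE]
    }
    gl <- unlist(strsplit(df$genes[nzchar(df$genes)], ";", fixed = TRUE))
    sort(unique(as.character(gl)))
  }
  if ("direction" %in% names(annotated)) {
    lapply(split(annotated, annotated$direction), pick)
  } else {
    pick(annotated)
  }
}

#' Read a GMT gene-set file
#' @param path GMT path (term, description, then member genes per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, with `N` universe genes, `K` of them in the term, `n`
#' candidate genes and `k` candidates in the term, the upper-tail
#' hypergeometric probability `P(X >= k)` is reported with a
#' Benjamini-Hochberg FDR alongside. Term gene lists are intersected with
#' the universe before testing; terms with no universe genes are dropped
#' with a message.
#'
#' @param candidates Character vector of candidate gene ids (non-empty,
#'   must be a subset of `universe`).
#' @param universe Character vector of universe gene ids.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param alpha Raw-p significance cutoff for the `significant` flag
#'   (default 0.05).
#' @return `data.frame(term_id, k, K, n, N, p, fdr, significant, genes)`
#'   sorted by `p`.
#' @export
hypergeom_enrich <- function(candidates, universe, gene_sets, alpha = 0.05) {
  candidates <- unique(candidates)
  universe <- unique(universe)
  if (!length(candidates)) stopf("empty candidate gene set")
  extra <- setdiff(candidates, universe)
  if (length(extra)) {
    stopf("candidate gene '%s' is not in the universe", extra[1])
  }
  sets <- lapply(gene_sets, intersect, universe)
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty)) {
    message(sprintf(
      "dropping %d term(s) with no universe genes", sum(empty)
    ))
    sets <- sets[!empty]
  }
  n <- length(candidates)
  bigN <- length(universe)
  rows <- lapply(names(sets), function(term) {
    set <- sets[[term]]
    k <- length(intersect(candidates, set))
    bigK <- length(set)
    p <- stats::phyper(k - 1, bigK, bigN - bigK, n, lower.tail = FALSE)
    data.frame(
      term_id = term, k = k, K = bigK, n = n, N = bigN, p = p,
      genes = paste(sort(intersect(candidates, set)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$term_id), c(
    "term_id", "k", "K", "n", "N", "p", "fdr", "significant", "genes"
  )]
  rownames(res) <- NULL
  res
}
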