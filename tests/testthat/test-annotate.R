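# Gene-model loading, SNP annotation, candidate genes, enrichment.

variants_at <- function(pos, chrom = "1") {
  data.frame(
    chrom = chrom, pos = as.integer(pos),
    vid = paste0("snp", seq_along(pos)),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
}

test_that("GFF3 and BED12 fixtures load to the same intervals", {
  fx <- write_gene_fixture()
  a <- load_gene_models(fx$gff)
  b <- load_gene_models(fx$bed)
  expect_equal(a$genes$gene_id, c("geneA", "geneB", "geneC"))
  expect_equal(a$genes[, c("gene_id", "chrom", "start", "end", "strand")],
    b$genes[, c("gene_id", "chrom", "start", "end", "strand")]
  )
  expect_equal(a$genes$start, c(1001, 5001, 10001))
  expect_equal(a$genes$end, c(2000, 6000, 12000))
  ea <- a$exons[order(a$exons$start), ]
  eb <- b$exons[order(b$exons$start), ]
  expect_equal(ea$start, eb$start)
  expect_equal(ea$end, eb$end)
  expect_equal(ea$start, c(1001, 5001, 5801, 10001))
  expect_equal(ea$end, c(2000, 5200, 6000, 12000))
})

test_that("category precedence follows the annotation rules", {
  fx <- write_gene_fixture()
  models <- load_gene_models(fx$gff)
  v <- variants_at(c(
    1500, # inside geneA's single full-length exon -> exonic
    5100, # inside geneB exon 1 -> exonic
    5500, # inside geneB between exons -> intronic
    700, # 301 bp before geneA start (+) -> upstream
    2800, # 800 bp after geneA end (+) -> downstream
    6500, # geneB is '-': 500 bp past its 3' end (start side is 5001);
    # 6001-7000 is geneB's upstream flank -> upstream
    4500, # geneB '-': 4001-5000 is its downstream flank -> downstream
    40000 # far from everything -> intergenic
  ))
  ann <- annotate_snps(v, models, flank = 1000)
  expect_equal(ann$category, c(
    "exonic", "exonic", "intronic", "upstream", "downstream",
    "upstream", "downstream", "intergenic"
  ))
  expect_equal(ann$genes[1], "geneA")
  expect_equal(ann$genes[2], "geneB")
  # intergenic SNP records its flanking gene within the search limit
  expect_equal(ann$genes[8], "geneB")
})

test_that("a SNP in two flanks at once is upstream/downstream", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=geneA",
    "1\ttest\tgene\t3700\t4500\t.\t+\t.\tID=geneB"
  ), gff)
  models <- load_gene_models(gff)
  # 800 bp after geneA's end and 900 bp before geneB's start
  ann <- annotate_snps(variants_at(2800), models, flank = 1000)
  expect_equal(ann$category, "upstream/downstream")
  expect_setequal(strsplit(ann$genes, ";")[[1]], c("geneA", "geneB"))
})

test_that("categories partition any SNP set and match a brute-force scan", {
  set.seed(55)
  ngene <- 20
  starts <- sort(sample.int(2e5, ngene))
  genes <- data.frame(
    gene_id = paste0("g", seq_len(ngene)),
    name = paste0("g", seq_len(ngene)),
    chrom = "1", start = starts, end = starts + sample(500:3000, ngene),
    strand = sample(c("+", "-"), ngene, replace = TRUE),
    stringsAsFactors = FALSE
  )
  models <- structure(
    list(genes = genes[order(genes$chrom, genes$start), ],
      exons = data.frame(
        gene_id = character(), chrom = character(),
        start = integer(), end = integer(), stringsAsFactors = FALSE
      )),
    class = "gene_models"
  )
  v <- variants_at(sort(sample.int(2.2e5, 300)))
  ann <- annotate_snps(v, models, flank = 1000, max_flank_search = 1e6)

  counts <- category_counts(ann)
  expect_equal(sum(counts$n), nrow(v))
  expect_equal(counts$n[counts$category == "exonic"], 0L)

  flank <- 1000
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]
    inside <- genes$start <= pos & genes$end >= pos
    plus <- genes$strand == "+"
    up <- ifelse(plus,
      pos >= genes$start - flank & pos < genes$start,
      pos > genes$end & pos <= genes$end + flank
    )
    dn <- ifelse(plus,
      pos > genes$end & pos <= genes$end + flank,
      pos >= genes$start - flank & pos < genes$start
    )
    want <- if (any(inside)) {
      "intronic"
    } else if (any(up) && any(dn)) {
      "upstream/downstream"
    } else if (any(up)) {
      "upstream"
    } else if (any(dn)) {
      "downstream"
    } else {
      "intergenic"
    }
    expect_equal(ann$category[i], want, label = paste("SNP at", pos))
    if (want == "intronic") {
      # genic SNPs carry only their containing gene(s): precedence
      expect_setequal(
        strsplit(ann$genes[i], ";")[[1]], unique(genes$gene_id[inside])
      )
    } else if (want %in% c("upstream", "downstream",
      "upstream/downstream")) {
      hits <- unique(genes$gene_id[up | dn])
      expect_setequal(strsplit(ann$genes[i], ";")[[1]], hits)
    }
  }
})

test_that("candidate genes deduplicate and honor the intergenic flag", {
  ann <- data.frame(
    vid = paste0("s", 1:5),
    chrom = "1", pos = 1:5,
    category = c(
      "intronic", "intronic", "upstream", "intergenic", "intergenic"
    ),
    genes = c("gA", "gA", "gB", "gC", ""),
    direction = c("hi", "hi", "hi", "hi", "lo"),
    stringsAsFactors = FALSE
  )
  withn <- candidate_genes(ann)
  expect_equal(withn$hi, c("gA", "gB", "gC"))
  expect_equal(withn$lo, character(0))
  without <- candidate_genes(ann, include_intergenic_neighbors = FALSE)
  expect_equal(without$hi, c("gA", "gB"))

  flat <- candidate_genes(ann[, -6])
  expect_equal(flat, c("gA", "gB", "gC"))
})

test_that("hypergeometric enrichment matches trivial and enumerated cases", {
  universe <- paste0("g", 1:10)
  sets <- list(all = universe, half = paste0("g", 1:5))
  res <- hypergeom_enrich(paste0("g", 1:5), universe, sets)
  expect_equal(res$p[res$term_id == "all"], 1)
  # N = 10, K = 5, n = 5, k = 5 -> 1 / C(10,5)
  expect_equal(
    res$p[res$term_id == "half"], 1 / choose(10, 5),
    tolerance = 1e-12
  )
  expect_true(res$significant[res$term_id == "half"])

  # k = 0: upper tail includes 0, so p = 1
  res0 <- hypergeom_enrich(paste0("g", 6:10), universe,
    list(half = paste0("g", 1:5))
  )
  expect_equal(res0$p, 1)

  expect_error(hypergeom_enrich(character(0), universe, sets), "empty")
  expect_error(hypergeom_enrich("gX", universe, sets), "universe")
})

test_that("enrichment p-values agree with direct summation for N <= 40", {
  set.seed(66)
  worst <- 0
  for (rep in 1:25) {
    N <- sample(8:40, 1)
    universe <- paste0("g", seq_len(N))
    n <- sample(2:(N - 1), 1)
    K <- sample(1:N, 1)
    candidates <- sample(universe, n)
    term <- sample(universe, K)
    res <- hypergeom_enrich(candidates, universe, list(t = term))
    k <- length(intersect(candidates, term))
    worst <- max(worst, abs(res$p - oracle_hyper(k, K, n, N)))
    expect_equal(res$k, k)
  }
  expect_lt(worst, 1e-12)
})

test_that("GMT parsing feeds enrichment end to end", {
  gmt <- write_gmt_fixture(
    list(term1 = c("geneA", "geneB"), term2 = c("geneC", "geneZ")),
    tempfile(fileext = ".gmt")
  )
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("term1", "term2"))
  fx <- write_gene_fixture()
  models <- load_gene_models(fx$gff)
  expect_message(
    res <- hypergeom_enrich(
      "geneA", models$genes$gene_id,
      list(term1 = c("geneA", "geneB"), missing = "geneZ")
    ),
    "no universe genes"
  )
  expect_equal(res$term_id, "term1")
  expect_equal(res$N, 3L)
})
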