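# Pipeline orchestration: QC -> structure -> LD -> scan -> annotate ->
# enrich from a single config, plus the phenotype utilities.

#' Build and validate a pipeline configuration
#'
#' Either supply genotype input (`vcf` or `ped`/`map` plus `popmap`) or a
#' `simulate` list of [sim_params()] overrides; the two are mutually
#' exclusive. The numerator population of the diversity ratio must be named
#' explicitly -- sweep directionality depends on it.
#'
#' @param outdir Run directory (created; contents are overwritten).
#' @param numerator_population Population whose diversity forms the ratio
#'   numerator.
#' @param vcf,ped,map,popmap Optional input paths.
#' @param simulate Optional list of [sim_params()] overrides (use `list()`
#'   for the defaults).
#' @param qc List of [qc_filter()] overrides.
#' @param window,step,top_frac,min_snps Scan settings (bp, bp, tail
#'   fraction, minimum SNPs per window).
#' @param fst_estimator `"nei"` or `"wc"`.
#' @param combine `"intersect"` or `"union"` of the two sweep criteria.
#' @param ld List: `max_dist`, `bin_width`, `equalize_n` (logical),
#'   `r2_threshold`.
#' @param chrom_len Optional chromosome length(s) passed to the scan.
#' @param gene_models,gene_sets Optional paths (GFF3/BED12 and GMT) enabling
#'   the annotation and enrichment stages.
#' @param flank,max_flank_search Annotation flank settings in bp.
#' @param seed Global seed; per-stage seeds are derived by fixed offsets.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            numerator_population = "highland",
                            vcf = NULL, ped = NULL, map = NULL,
                            popmap = NULL,
                            simulate = NULL,
                            qc = list(),
                            window = 5e6, step = 1e5,
                            top_frac = 0.01, min_snps = 2,
                            fst_estimator = "nei",
                            combine = "intersect",
                            ld = list(),
                            chrom_len = NULL,
                            gene_models = NULL, gene_sets = NULL,
                            flank = 1000, max_flank_search = 1e6,
                            seed = 1L) {
  cfg <- list(
    outdir = outdir, numerator_population = numerator_population,
    vcf = vcf, ped = ped, map = map, popmap = popmap,
    simulate = simulate, qc = qc,
    window = window, step = step, top_frac = top_frac,
    min_snps = min_snps, fst_estimator = fst_estimator, combine = combine,
    ld = utils::modifyList(
      list(max_dist = 5e5, bin_width = 1e3, equalize_n = TRUE,
        r2_threshold = 0.3),
      ld
    ),
    chrom_len = chrom_len,
    gene_models = gene_models, gene_sets = gene_sets,
    flank = flank, max_flank_search = max_flank_search,
    seed = as.integer(seed)
  )
  has_input <- !is.null(cfg$vcf) || !is.null(cfg$ped)
  if (has_input && !is.null(cfg$simulate)) {
    stopf("give either genotype input or a simulate block, not both")
  }
  if (!has_input && is.null(cfg$simulate)) {
    stopf("no input: supply vcf or ped/map, or a simulate block")
  }
  if (has_input && is.null(cfg$popmap)) stopf("popmap is required")
  stopifnot(
    cfg$window >= cfg$step, cfg$top_frac > 0, cfg$top_frac < 0.5,
    cfg$min_snps >= 0, cfg$fst_estimator %in% c("nei", "wc"),
    cfg$combine %in% c("intersect", "union")
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Executes input (or simulation), QC, population structure, LD decay,
#' the sweep scan, and -- when gene models are configured -- annotation and
#' enrichment, writing per-stage TSV/BED/JSON artifacts and a manifest with
#' the config and the MD5 checksum of every output. Reruns with identical
#' config and inputs are bit-identical.
#'
#' @param cfg A [pipeline_config()] (or a YAML path).
#' @return The manifest list, invisibly; artifacts live under
#'   `cfg$outdir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$outdir, ...)
  artifacts <- character(0)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[sweepscan] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  # validate the numerator label against the declared populations before
  # touching any genotype data
  run_stage("validate", {
    declared <- if (!is.null(cfg$popmap)) {
      unique(read_popmap(cfg$popmap)$population)
    } else {
      params <- do.call(sim_params, utils::modifyList(
        cfg$simulate %||% list(), list(seed = cfg$seed)
      ))
      params$pop_labels
    }
    if (!cfg$numerator_population %in% declared) {
      stopf(
        "numerator population '%s' not among declared labels: %s",
        cfg$numerator_population, paste(declared, collapse = ", ")
      )
    }
  })

  truth <- NULL
  g <- run_stage("input", {
    if (!is.null(cfg$simulate)) {
      params <- do.call(sim_params, utils::modifyList(
        cfg$simulate, list(seed = cfg$seed)
      ))
      sim <- simulate_genotypes(params)
      truth <- sim$truth
      write_vcf(sim$genotypes, out("input.vcf"))
      write_popmap(sim$genotypes$samples, out("popmap.tsv"))
      write_truth_bed(truth, out("truth.bed"))
      phen <- simulate_phenotypes(sim$genotypes$samples,
        seed = cfg$seed + 1L
      )
      write_tsv(phen, out("phenotypes.tsv"))
      artifacts <- c(
        artifacts, "input.vcf", "popmap.tsv", "truth.bed", "phenotypes.tsv"
      )
      say(
        "simulated %d samples x %d variants (seed %d)",
        nrow(sim$genotypes$calls), ncol(sim$genotypes$calls), cfg$seed
      )
      sim$genotypes
    } else if (!is.null(cfg$vcf)) {
      read_vcf(cfg$vcf, cfg$popmap)
    } else {
      read_plink_text(cfg$ped, cfg$map, cfg$popmap)
    }
  })

  pops <- pop_labels(g)
  if (!cfg$numerator_population %in% pops) {
    stopf(
      "numerator population '%s' not among labels: %s",
      cfg$numerator_population, paste(pops, collapse = ", ")
    )
  }
  if (length(pops) != 2) {
    stopf("pipeline expects exactly 2 populations, found %d", length(pops))
  }
  pop1 <- cfg$numerator_population
  pop2 <- setdiff(pops, pop1)

  qcres <- run_stage("qc", do.call(qc_filter, c(list(g), cfg$qc)))
  g <- qcres$genotypes
  write_qc_report(qcres$report, out("qc_report.tsv"))
  write_vcf(g, out("filtered.vcf"))
  artifacts <- c(artifacts, "qc_report.tsv", "filtered.vcf")
  say(
    "QC: retained %d of %d variants",
    qcres$report$n_retained, qcres$report$n_input
  )

  run_stage("popstruct", {
    pca <- pca_genotypes(g)
    write_pca(pca, out("pca_coords.tsv"), out("pca_variance.tsv"))
    d <- ibs_distance(g)
    write_distance_matrix(d, out("ibs_matrix.tsv"))
    write_newick(nj_tree(d), out("nj_tree.nwk"))
    say(
      "structure: PC1 explains %.1f%% of variance",
      100 * pca$variance_explained[1]
    )
  })
  artifacts <- c(
    artifacts, "pca_coords.tsv", "pca_variance.tsv", "ibs_matrix.tsv",
    "nj_tree.nwk"
  )

  ld_summary <- run_stage("ld", {
    gl <- g
    if (isTRUE(cfg$ld$equalize_n)) {
      sizes <- table(gl$samples$population)
      n_eq <- min(sizes)
      for (p in names(sizes)[sizes > n_eq]) {
        gl <- downsample(gl, p, n_eq, seed = cfg$seed + 2L)
      }
      say("LD: equalized both populations to n = %d", n_eq)
    }
    summ <- list()
    for (p in c(pop1, pop2)) {
      curve <- ld_decay(gl, p,
        max_dist = cfg$ld$max_dist, bin_width = cfg$ld$bin_width
      )
      write_tsv(curve, out(sprintf("ld_decay_%s.tsv", p)))
      summ[[p]] <- r2_threshold_distance(curve, cfg$ld$r2_threshold)
    }
    summ
  })
  artifacts <- c(
    artifacts, sprintf("ld_decay_%s.tsv", c(pop1, pop2))
  )

  calls <- run_stage("scan", {
    windows <- sweep_scan(g, pop1, pop2,
      window = cfg$window, step = cfg$step, chrom_len = cfg$chrom_len,
      estimator = cfg$fst_estimator
    )
    calls <- call_sweeps(windows,
      top_frac = cfg$top_frac,
      min_snps = cfg$min_snps, combine = cfg$combine
    )
    write_tsv(calls$windows, out("windows.tsv"))
    thr <- calls$thresholds
    jsonlite::write_json(
      thr, out("thresholds.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_region_bed(calls, out("regions"))
    snps <- candidate_snps(calls, g)
    write_tsv(snps, out("candidate_snps.tsv"))
    say(
      "scan: %d/%d windows selected (%s/%s); %d candidate SNPs",
      sum(calls$windows[[paste0("selected_", pop1)]]),
      sum(calls$windows[[paste0("selected_", pop2)]]),
      pop1, pop2, nrow(snps)
    )
    calls
  })
  artifacts <- c(
    artifacts, "windows.tsv", "thresholds.json",
    sprintf("regions_%s.bed", c(pop1, pop2)), "candidate_snps.tsv"
  )

  if (!is.null(truth)) {
    rec <- sweep_recovery(calls, truth)
    say(
      "recovery vs planted truth: precision %.2f, recall %.2f",
      rec$precision, rec$recall
    )
  }

  if (!is.null(cfg$gene_models)) {
    run_stage("annotate", {
      models <- load_gene_models(cfg$gene_models)
      ann_all <- annotate_snps(g, models,
        flank = cfg$flank,
        max_flank_search = cfg$max_flank_search
      )
      write_tsv(ann_all, out("annotation.tsv"))
      write_tsv(category_counts(ann_all), out("category_counts.tsv"))
      snps <- candidate_snps(calls, g)
      ann_cand <- merge(snps, ann_all[, c("vid", "category", "genes")],
        by = "vid", sort = FALSE
      )
      write_tsv(ann_cand, out("candidate_annotation.tsv"))
      cand <- candidate_genes(ann_cand)
      if (!is.null(cfg$gene_sets)) {
        sets <- read_gmt(cfg$gene_sets)
        universe <- models$genes$gene_id
        for (p in names(cand)) {
          if (!length(cand[[p]])) next
          enr <- hypergeom_enrich(cand[[p]], universe, sets)
          write_tsv(enr, out(sprintf("enrichment_%s.tsv", p)))
          artifacts <- c(artifacts, sprintf("enrichment_%s.tsv", p))
        }
      }
      say(
        "annotation: %s candidate gene(s)",
        paste(sprintf("%s=%d", names(cand), lengths(cand)), collapse = ", ")
      )
    })
    artifacts <- c(
      artifacts, "annotation.tsv", "category_counts.tsv",
      "candidate_annotation.tsv"
    )
  }

  writeLines(log_lines, out("run.log"))
  checks <- tools::md5sum(out(sort(unique(artifacts))))
  names(checks) <- basename(names(checks))
  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    config = unclass(cfg),
    ld_r2_threshold_distance = ld_summary,
    artifacts = as.list(checks)
  )
  jsonlite::write_json(
    manifest, out("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(manifest)
}

#' Average daily weight gain between the 20 kg and 50 kg stages
#'
#' `(50 - 20) / (age_at_50kg - age_at_20kg)` in kg/day.
#'
#' @param age_at_20kg,age_at_50kg Ages in days (vectorized);
#'   `age_at_50kg` must exceed `age_at_20kg`.
#' @return Average daily gain in kg/day.
#' @examples
#' adwg(100, 200) # 0.3 kg/day
#' @export
adwg <- function(age_at_20kg, age_at_50kg) {
  if (any(age_at_50kg <= age_at_20kg)) {
    stopf("age_at_50kg must exceed age_at_20kg")
  }
  (50 - 20) / (age_at_50kg - age_at_20kg)
}

#' Two-group phenotype comparison
#'
#' Unpaired two-tailed Student's t-test (pooled variance by default; Welch
#' via `var_equal = FALSE`), with per-group medians reported. Two groups
#' with zero pooled variance and equal means return `t = 0, p = 1` by
#' convention; zero variance with unequal means is an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student's test if `TRUE` (default).
#' @return List with `t`, `df`, `p`, `medians` (named by deparsed inputs).
#' @export
compare_phenotypes <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  meds <- c(median_x = stats::median(x), median_y = stats::median(y))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(
        t = 0, df = length(x) + length(y) - 2, p = 1, medians = meds
      ))
    }
    stopf("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, medians = meds
  )
}
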