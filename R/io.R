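#' Write a paired cohort (and optional truth tables) to a directory
#'
#' Tab-separated layout: expression and logR matrices (feature id first
#' column, sample ids in the header), BED-like maps (chrom, 0-based start,
#' end, id), covariate and survival tables, the configuration as a flat
#' `key=value` file, and truth tables when supplied.
#'
#' @param cohort a `paired_cohort`.
#' @param truth optional truth list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, truth = NULL, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$expression_an, file.path(dir, "expression_an.tsv"))
  write_matrix_tsv(cohort$expression_tu, file.path(dir, "expression_tu.tsv"))
  write_matrix_tsv(cohort$logr_an, file.path(dir, "logr_an.tsv"))
  write_matrix_tsv(cohort$logr_tu, file.path(dir, "logr_tu.tsv"))
  write_bed_map(cohort$gene_map, file.path(dir, "gene_map.bed"))
  write_bed_map(cohort$snp_map, file.path(dir, "snp_map.bed"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    keys <- names(cfg)
    writeLines(paste0(keys, "=", vapply(cfg, function(v)
      paste(format(v, scientific = FALSE), collapse = ","), "")),
      file.path(dir, "config.txt"))
  }
  if (!is.null(truth)) {
    td <- file.path(dir, "truth")
    dir.create(td, showWarnings = FALSE)
    utils::write.table(truth$scnv_segments, file.path(td, "segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(truth$cis_driven_genes, file.path(td, "cis_driven_genes.txt"))
    writeLines(truth$disrupted_genes, file.path(td, "disrupted_genes.txt"))
    utils::write.table(truth$disrupted_pairs,
                       file.path(td, "disrupted_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$created_pairs,
                       file.path(td, "created_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_membership(truth$an_modules, file.path(td, "an_modules.tsv"))
    write_membership(truth$tu_modules, file.path(td, "tu_modules.tsv"))
    write_membership(truth$hotspot_regulons,
                     file.path(td, "hotspot_regulons.tsv"))
    if (!is.null(truth$hotspots)) {
      utils::write.table(truth$hotspots, file.path(td, "hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(truth$survival_genes_an,
               file.path(td, "survival_genes_an.txt"))
    writeLines(truth$survival_genes_tu,
               file.path(td, "survival_genes_tu.txt"))
  }
  invisible(dir)
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_bed_map <- function(map, path) {
  bed <- data.frame(chrom = map$chrom, start = map$pos - 1L, end = map$pos,
                    id = map$id, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

write_membership <- function(sets, path) {
  if (!length(sets)) {
    writeLines("gene\tset", path)
    return(invisible(path))
  }
  nm <- names(sets) %||% as.character(seq_along(sets))
  if (is.null(names(sets))) nm <- as.character(seq_along(sets))
  df <- data.frame(gene = unlist(sets, use.names = FALSE),
                   set = rep(nm, vapply(sets, length, 0L)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row %d (%s), column %d (%s)",
                 basename(path), bad[1L], ids[bad[1L]], bad[2L],
                 colnames(m)[bad[2L]]), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

read_bed_map <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "id"),
                           stringsAsFactors = FALSE)
  data.frame(id = bed$id, chrom = bed$chrom, pos = bed$end,
             stringsAsFactors = FALSE)
}

#' Load a paired cohort from the standard layout
#'
#' Reads the files written by [write_cohort()] and validates cross-file
#' consistency: both tissues must share gene and sample indices, maps must
#' cover the matrices, and covariates/survival must cover every sample.
#'
#' @param dir cohort directory.
#' @return a `paired_cohort`.
#' @export
load_cohort <- function(dir) {
  expression_an <- read_matrix_tsv(file.path(dir, "expression_an.tsv"))
  expression_tu <- read_matrix_tsv(file.path(dir, "expression_tu.tsv"))
  logr_an <- read_matrix_tsv(file.path(dir, "logr_an.tsv"))
  logr_tu <- read_matrix_tsv(file.path(dir, "logr_tu.tsv"))
  gene_map <- read_bed_map(file.path(dir, "gene_map.bed"))
  snp_map <- read_bed_map(file.path(dir, "snp_map.bed"))
  covariates <- utils::read.table(file.path(dir, "covariates.tsv"),
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  survival <- utils::read.table(file.path(dir, "survival.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  samples <- colnames(expression_an)
  check_same <- function(what, got, want) {
    miss <- setdiff(want, got)
    extra <- setdiff(got, want)
    if (length(miss) || length(extra)) {
      stop(sprintf("%s inconsistent: missing [%s], unexpected [%s]", what,
                   paste(utils::head(miss, 5L), collapse = ", "),
                   paste(utils::head(extra, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  check_same("TU expression samples", colnames(expression_tu), samples)
  check_same("AN logR samples", colnames(logr_an), samples)
  check_same("TU logR samples", colnames(logr_tu), samples)
  check_same("covariate samples", covariates$sample, samples)
  check_same("survival samples", survival$sample, samples)
  check_same("gene map entries", gene_map$id, rownames(expression_an))
  check_same("SNP map entries", snp_map$id, rownames(logr_an))
  if (any(survival$time <= 0)) stop("survival times must be positive",
                                    call. = FALSE)
  structure(list(expression_an = expression_an,
                 expression_tu = expression_tu,
                 logr_an = logr_an, logr_tu = logr_tu,
                 gene_map = gene_map, snp_map = snp_map,
                 covariates = covariates, survival = survival,
                 config = NULL), class = "paired_cohort")
}

#' Pipeline configuration
#'
#' Gathers every threshold applied along the pipeline; unknown keys are
#' rejected (they would be unused arguments).
#'
#' @param q_threshold,goc_loc_fraction,correlation_method,n_label_permutations,block_size
#'   differential-connectivity settings ([meta_config()]).
#' @param window,step marker smoothing.
#' @param cis_max_distance cis window (bp).
#' @param r_cutoff gene-marker correlation cutoff.
#' @param hotspot_min_genes hotspot associated-gene minimum.
#' @param n_pairing_permutations pairing permutations for the marker FDR.
#' @param entry_p stepwise entry p.
#' @param survival_n_perm,target_fdr survival screen settings.
#' @param betas,fit_min,cut_height,min_module_size coexpression settings.
#' @param gene_sets optional GMT path for enrichment reports.
#' @param seed master seed.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(q_threshold = 80, goc_loc_fraction = 0.90,
                            correlation_method = "spearman",
                            n_label_permutations = 1L, block_size = 1000L,
                            window = 40L, step = 20L, cis_max_distance = 5e6,
                            r_cutoff = 0.3, hotspot_min_genes = 500L,
                            n_pairing_permutations = 10L, entry_p = 5.1e-6,
                            survival_n_perm = 100L, target_fdr = 0.1,
                            betas = seq(1, 12, by = 0.5), fit_min = 0.7,
                            cut_height = 0.95, min_module_size = 30L,
                            gene_sets = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full paired-cohort analysis pipeline
#'
#' Stages, in order: robust covariate adjustment per tissue; paired
#' differential expression; differential-connectivity scan with
#' label-permutation FDR; sCNV marker smoothing, cis assignment, gene-marker
#' association with pairing-permutation FDR, hotspot detection, and stepwise
#' variance decomposition (with a pairing-permuted control); Cox survival
#' screens of AN genes, TU genes and markers with permutation FDR
#' thresholds; cross-tissue overlap; enrichment cross-tests; per-tissue
#' coexpression modules and their overlap map. Each stage is cached as an
#' RDS under `out_dir` and reused on rerun (`resume = TRUE`), so a run can
#' be resumed after deleting any stage's file.
#'
#' @param cohort a `paired_cohort` (or a directory for [load_cohort()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory for stage caches and reports; NULL for
#'   in-memory only.
#' @param resume reuse cached stage outputs when present.
#' @return named list with every stage result (class `hccnet_pipeline`).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         resume = TRUE) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  stopifnot(inherits(cohort, "paired_cohort"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    path <- if (!is.null(out_dir)) file.path(out_dir,
                                             paste0("stage_", name, ".rds"))
    if (!is.null(path) && resume && file.exists(path)) {
      message("[", name, "] reusing cached stage")
      return(readRDS(path))
    }
    message("[", name, "] running")
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    if (!is.null(path)) saveRDS(value, path)
    value
  }
  mc <- meta_config(q_threshold = config$q_threshold,
                    goc_loc_fraction = config$goc_loc_fraction,
                    correlation_method = config$correlation_method,
                    n_label_permutations = config$n_label_permutations,
                    block_size = config$block_size, seed = config$seed)

  adj <- stage("adjust", list(
    an = robust_covariate_adjust(cohort$expression_an, cohort$covariates),
    tu = robust_covariate_adjust(cohort$expression_tu, cohort$covariates)))
  paired <- stage("paired_de", paired_differential_expression(
    cohort$expression_an, cohort$expression_tu))
  diffconn <- stage("diffconn", {
    fit <- diffcorr_scan(adj$an, adj$tu, mc)
    fdr <- label_permutation_fdr(adj$an, adj$tu, mc)
    degree <- tryCatch(degree_power_law(fit), error = function(e) NULL)
    list(fit = fit, fdr = fdr, degree = degree)
  })
  scnv <- stage("scnv", {
    markers <- smooth_logr(cohort$logr_tu, cohort$snp_map,
                           config$window, config$step)
    cis <- nearest_cis_marker(cohort$gene_map, markers,
                              config$cis_max_distance)
    correlations <- gene_marker_correlations(adj$tu, markers,
                                             config$r_cutoff,
                                             cohort$gene_map)
    pair_fdr <- pairing_permutation_fdr(adj$tu, markers, config$r_cutoff,
                                        config$n_pairing_permutations,
                                        config$seed)
    hotspots <- detect_hotspots(correlations, markers, cohort$gene_map,
                                config$hotspot_min_genes, config$r_cutoff)
    models <- stepwise_variance_all(adj$tu, markers, config$entry_p)
    pm_markers <- permute_marker_samples(markers, config$seed)
    pm_models <- stepwise_variance_all(adj$tu, pm_markers, config$entry_p)
    summary <- variance_summary(models, cis, adj$tu, markers,
                                permuted_models = pm_models,
                                permuted_markers = pm_markers)
    list(markers = markers, cis = cis, correlations = correlations,
         pair_fdr = pair_fdr, hotspots = hotspots, models = models,
         pm_models = pm_models, summary = summary)
  })
  surv <- stage("survival", {
    an <- cox_screen_fdr(adj$an, cohort$survival, config$survival_n_perm,
                         config$target_fdr, config$seed, tissue = "AN")
    tu <- cox_screen_fdr(adj$tu, cohort$survival, config$survival_n_perm,
                         config$target_fdr, config$seed, tissue = "TU")
    mk <- cox_screen_fdr(scnv$markers$values, cohort$survival,
                         config$survival_n_perm, config$target_fdr,
                         config$seed, tissue = "markers")
    overlap <- cross_tissue_overlap(
      an$results$feature[an$results$significant],
      tu$results$feature[tu$results$significant],
      nrow(cohort$expression_an))
    list(an = an, tu = tu, markers = mk, overlap = overlap)
  })
  enrich <- stage("enrichment", {
    universe <- cohort$gene_map$id
    diff_genes <- diffconn$fit$genes$gene[
      diffconn$fit$genes$diff_connection_count > 0]
    cis_genes <- scnv$cis$gene[!is.na(scnv$cis$marker)]
    sig_an <- surv$an$results$feature[surv$an$results$significant]
    sig_tu <- surv$tu$results$feature[surv$tu$results$significant]
    tests <- list(
      diff_vs_cis = fisher_enrichment(diff_genes, cis_genes, universe),
      an_surv_vs_diff = fisher_enrichment(sig_an, diff_genes, universe),
      tu_surv_vs_diff = fisher_enrichment(sig_tu, diff_genes, universe))
    marker_strata <- stats::setNames(
      ifelse(surv$markers$results$significant, "predictive",
             "not_predictive"),
      surv$markers$results$feature)
    assoc <- split(scnv$correlations$table$gene,
                   scnv$correlations$table$marker)
    adj_enr <- list(
      an_survival = marker_adjusted_enrichment(sig_an, assoc, universe,
                                               marker_strata),
      tu_survival = marker_adjusted_enrichment(sig_tu, assoc, universe,
                                               marker_strata))
    signature <- NULL
    if (!is.null(config$gene_sets)) {
      sets <- read_gmt(config$gene_sets)
      sets <- lapply(sets, function(s) intersect(s, universe))
      signature <- lapply(sets, function(s) list(
        vs_diff = fisher_enrichment(s, diff_genes, universe),
        vs_an_surv = fisher_enrichment(s, sig_an, universe),
        vs_cis = fisher_enrichment(s, cis_genes, universe)))
    }
    list(tests = tests, marker_adjusted = adj_enr, signature = signature)
  })
  coexpr <- stage("coexpression", {
    an <- coexpression_network(adj$an, betas = config$betas,
                               fit_min = config$fit_min,
                               cut_height = config$cut_height,
                               min_size = config$min_module_size,
                               tissue = "AN")
    tu <- coexpression_network(adj$tu, betas = config$betas,
                               fit_min = config$fit_min,
                               cut_height = config$cut_height,
                               min_size = config$min_module_size,
                               tissue = "TU")
    list(an = an, tu = tu, overlap = module_overlap_map(an, tu))
  })
  results <- structure(list(
    cohort = cohort, config = config, adjusted = adj, paired_de = paired,
    diffconn = diffconn, scnv = scnv, survival = surv, enrichment = enrich,
    coexpression = coexpr), class = "hccnet_pipeline")
  if (!is.null(out_dir)) write_reports(results, out_dir)
  results
}

#' @export
print.hccnet_pipeline <- function(x, ...) {
  cat("hccnet pipeline results\n")
  print(x$diffconn$fit)
  print(x$scnv$hotspots)
  cat(sprintf("  survival: %d AN / %d TU significant genes (FDR %.2g)\n",
              sum(x$survival$an$results$significant),
              sum(x$survival$tu$results$significant),
              x$survival$an$target_fdr))
  print(x$coexpression$an)
  print(x$coexpression$tu)
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits a per-gene master table (location, paired test, differential
#' connectivity with GOC/LOC counts, cis marker and correlation, stepwise
#' adjusted R^2 and marker count, survival p-values and significance flags,
#' module memberships), a sorted pair-level table, marker and hotspot
#' reports, variance-summary tables and the module overlap map, all as TSV.
#'
#' @param results a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- results$cohort
  genes <- co$gene_map$id
  dm <- results$diffconn$fit$genes
  an_part <- results$coexpression$an$partition
  tu_part <- results$coexpression$tu$partition
  cis <- results$scnv$cis
  cis_cc <- cis_correlations(results)
  sv_an <- results$survival$an$results
  sv_tu <- results$survival$tu$results
  vm <- results$scnv$models$summary
  master <- data.frame(
    gene = genes,
    chrom = co$gene_map$chrom,
    pos = co$gene_map$pos,
    pval_tu_vs_an = results$paired_de$p[match(genes, results$paired_de$gene)],
    connectivity = dm$diff_connection_count[match(genes, dm$gene)],
    n_goc = dm$goc_count[match(genes, dm$gene)],
    n_loc = dm$loc_count[match(genes, dm$gene)],
    class = dm$class[match(genes, dm$gene)],
    cis_marker = cis$marker[match(genes, cis$gene)],
    cis_cc = cis_cc[match(genes, names(cis_cc))],
    adjusted_r2 = vm$adj_r2[match(genes, vm$gene)],
    n_markers_in_model = vm$n_markers[match(genes, vm$gene)],
    pval_an_survival = sv_an$p[match(genes, sv_an$feature)],
    sig_an_survival = as.integer(sv_an$significant[match(genes,
                                                         sv_an$feature)]),
    pval_tu_survival = sv_tu$p[match(genes, sv_tu$feature)],
    sig_tu_survival = as.integer(sv_tu$significant[match(genes,
                                                         sv_tu$feature)]),
    an_module = an_part$module[match(genes, an_part$gene)],
    tu_module = tu_part$module[match(genes, tu_part$gene)],
    stringsAsFactors = FALSE)
  utils::write.table(master, file.path(dir, "gene_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pairs <- results$diffconn$fit$pairs
  pairs <- pairs[order(pairs$gene_i, pairs$gene_j), ]
  utils::write.table(pairs, file.path(dir, "differential_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- results$scnv$correlations$marker_counts
  mk$pval_survival <- results$survival$markers$results$p[
    match(mk$marker, results$survival$markers$results$feature)]
  mk$sig_survival <- as.integer(results$survival$markers$results$significant[
    match(mk$marker, results$survival$markers$results$feature)])
  utils::write.table(mk, file.path(dir, "marker_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$scnv$hotspots$hotspots,
                     file.path(dir, "hotspots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$scnv$summary$r2_counts,
                     file.path(dir, "variance_r2_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$coexpression$overlap,
                     file.path(dir, "module_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$diffconn$fdr,
                     file.path(dir, "diffconn_fdr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Pearson correlation between each gene and its assigned cis marker
cis_correlations <- function(results) {
  cis <- results$scnv$cis
  x <- adj_matrix(results$adjusted$tu)
  mv <- results$scnv$markers$values
  shared <- intersect(colnames(x), colnames(mv))
  out <- stats::setNames(rep(NA_real_, nrow(cis)), cis$gene)
  has <- which(!is.na(cis$marker))
  for (k in has) {
    out[k] <- stats::cor(x[cis$gene[k], shared], mv[cis$marker[k], shared])
  }
  out
}
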