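test_that("genome placement respects counts, allocation and determinism", {
  cfg <- sim_config(n_chromosomes = 2L, snps_per_chromosome = 100L,
                    n_genes = 50L, n_an_modules = 0L, n_tu_modules = 0L,
                    n_hotspots = 0L)
  maps <- simulate_genome(cfg)
  expect_equal(nrow(maps$snp_map), 200L)
  expect_equal(as.vector(table(maps$snp_map$chrom)), c(100L, 100L))
  maps2 <- simulate_genome(cfg)
  expect_identical(maps, maps2)

  cfg5 <- sim_config(n_genes = 1000L, n_chromosomes = 5L,
                     n_an_modules = 0L, n_tu_modules = 0L, n_hotspots = 0L)
  g5 <- simulate_genome(cfg5)$gene_map
  expect_true(all(table(g5$chrom) == 200L))
  # positions strictly increasing within chromosome
  for (ch in unique(g5$chrom)) {
    expect_false(is.unsorted(g5$pos[g5$chrom == ch], strictly = TRUE))
  }
  expect_error(sim_config(n_genes = 0L), "n_genes")
})

test_that("sCNV profiles carry segments in TU only, with faithful amplitudes", {
  cfg <- small_config(scnv_event_rate = 0, n_hotspots = 0L)
  maps <- simulate_genome(cfg)
  prof <- simulate_scnv_profiles(cfg, maps$snp_map)
  expect_equal(nrow(prof$segments), 0L)
  # zero-event case: TU is noise only, same scale as AN
  expect_equal(sd(prof$logr_tu), sd(prof$logr_an), tolerance = 0.05)
  expect_equal(sd(prof$logr_tu), cfg$logr_noise_sd, tolerance = 0.05)

  cfg2 <- small_config()
  maps2 <- simulate_genome(cfg2)
  prof2 <- simulate_scnv_profiles(cfg2, maps2$snp_map)
  seg <- prof2$segments
  expect_gt(nrow(seg), 0L)
  # mean logR over each segment's SNPs recovers its amplitude
  for (k in utils::head(seq_len(nrow(seg)), 10L)) {
    rows <- which(maps2$snp_map$chrom == seg$chrom[k])
    idx <- rows[seg$start_snp[k]:seg$end_snp[k]]
    others <- seg[seg$sample == seg$sample[k] & seq_len(nrow(seg)) != k, ]
    # skip segments overlapped by another event in the same sample
    if (any(others$chrom == seg$chrom[k])) next
    m <- mean(prof2$logr_tu[idx, seg$sample[k]])
    se <- cfg2$logr_noise_sd / sqrt(length(idx))
    expect_lt(abs(m - seg$amplitude[k]), 5 * se)
  }
  # minimum segment length honored
  expect_true(all(seg$end_snp - seg$start_snp + 1L >= cfg2$min_segment_snps |
                    seg$type == "hotspot"))
})

test_that("expression nulls and implanted effects behave as designed", {
  # null construction: no implanted differential structure
  cfg0 <- small_config(cis_effect = 0, n_hotspots = 1L,
                       disruption_fraction = 0, n_tu_modules = 1L)
  g0 <- generate_cohort(cfg0)
  expect_equal(length(g0$truth$disrupted_genes), 0L)
  expect_equal(nrow(g0$truth$disrupted_pairs), 0L)
  # an intact module pair correlates similarly in both tissues
  m1 <- g0$truth$an_modules[[1L]]
  ra <- cor(g0$cohort$expression_an[m1[1L], ], g0$cohort$expression_an[m1[2L], ])
  rt <- cor(g0$cohort$expression_tu[m1[1L], ], g0$cohort$expression_tu[m1[2L], ])
  expect_gt(ra, 0.5)
  expect_gt(rt, 0.5)

  # cis-driven gene correlates with its local smoothed marker
  cfg1 <- sim_config(cis_effect = 0.8, n_an_modules = 0L, n_tu_modules = 0L,
                     n_hotspots = 0L)
  g1 <- generate_cohort(cfg1)
  mk <- smooth_logr(g1$cohort$logr_tu, g1$cohort$snp_map)
  cis <- nearest_cis_marker(g1$cohort$gene_map, mk)
  picks <- which(g1$cohort$gene_map$id %in% g1$truth$cis_driven_genes &
                   !is.na(cis$marker))[1:20]
  rs <- vapply(picks, function(i) {
    cor(g1$cohort$expression_tu[cis$gene[i], ], mk$values[cis$marker[i], ])
  }, 0)
  expect_gt(median(rs), 0.5)

  # disrupted pairs: strong in AN, broken in TU
  gd <- generate_cohort(sim_config())
  dp <- utils::head(gd$truth$disrupted_pairs, 50L)
  r_an <- vapply(seq_len(nrow(dp)), function(k) {
    cor(gd$cohort$expression_an[dp$gene_i[k], ],
        gd$cohort$expression_an[dp$gene_j[k], ])
  }, 0)
  r_tu <- vapply(seq_len(nrow(dp)), function(k) {
    cor(gd$cohort$expression_tu[dp$gene_i[k], ],
        gd$cohort$expression_tu[dp$gene_j[k], ])
  }, 0)
  expect_gt(median(abs(r_an)), 0.5)
  expect_lt(median(abs(r_tu)), 0.2)
  # disrupted and created pairs never coincide
  key_d <- paste(gd$truth$disrupted_pairs$gene_i, gd$truth$disrupted_pairs$gene_j)
  key_c <- paste(gd$truth$created_pairs$gene_i, gd$truth$created_pairs$gene_j)
  expect_length(intersect(key_d, key_c), 0L)
})

test_that("survival simulation links hazard to designated genes", {
  # null hazard: screening is calibrated at ~5%
  cfg0 <- small_config(hazard_coef = 0)
  g0 <- generate_cohort(cfg0)
  scr <- cox_screen(g0$cohort$expression_an, g0$cohort$survival)
  expect_lt(mean(scr$results$p < 0.05), 0.12)

  # strong single-gene hazard is detected decisively
  cfg1 <- sim_config(n_pairs = 250L, n_genes = 300L, n_an_modules = 0L,
                     n_tu_modules = 0L, n_hotspots = 0L, cis_effect = 0,
                     survival_genes_an = 1L, survival_genes_tu = 0L,
                     hazard_coef = 1, censor_rate = 0.2)
  g1 <- generate_cohort(cfg1)
  expect_gte(sum(g1$cohort$survival$event), 150L)
  scr1 <- cox_screen(g1$cohort$expression_an, g1$cohort$survival)
  sg <- g1$truth$survival_genes_an
  expect_lt(scr1$results$p[scr1$results$feature == sg], 1e-6)

  # full censoring: no events, screening refuses to fit
  cfgc <- small_config(censor_rate = 1)
  gc <- generate_cohort(cfgc)
  expect_true(all(gc$cohort$survival$event == 0L))
  expect_error(cox_screen(gc$cohort$expression_an, gc$cohort$survival),
               "events")
  expect_error(sim_config(censor_rate = 1.5), "censor_rate")
})

test_that("generate_cohort is deterministic and truth matches config", {
  cfg <- small_config()
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$expression_tu, g2$cohort$expression_tu)
  expect_identical(g1$cohort$logr_tu, g2$cohort$logr_tu)
  expect_identical(g1$cohort$survival, g2$cohort$survival)
  expect_identical(g1$truth$disrupted_pairs, g2$truth$disrupted_pairs)

  expect_equal(nrow(g1$truth$hotspots), cfg$n_hotspots)
  expect_length(g1$truth$hotspot_regulons, cfg$n_hotspots)
  expect_length(g1$truth$survival_genes_an, cfg$survival_genes_an)
  expect_length(g1$truth$survival_genes_tu, cfg$survival_genes_tu)
  expect_length(g1$truth$an_modules, cfg$n_an_modules)
  # every truth gene exists in the map
  all_genes <- unlist(c(g1$truth$an_modules, g1$truth$tu_modules,
                        g1$truth$hotspot_regulons,
                        g1$truth$cis_driven_genes))
  expect_true(all(all_genes %in% g1$cohort$gene_map$id))
})

test_that("cohorts round-trip through the file layout without loss", {
  cfg <- small_config(n_pairs = 20L, n_genes = 40L, module_size = 10L,
                      hotspot_regulon_size = 5L)
  g <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, g$truth, dir)
  back <- load_cohort(dir)
  expect_equal(back$expression_an, g$cohort$expression_an, tolerance = 1e-10)
  expect_equal(back$logr_tu, g$cohort$logr_tu, tolerance = 1e-10)
  expect_identical(back$gene_map$id, g$cohort$gene_map$id)
  expect_identical(back$gene_map$pos, g$cohort$gene_map$pos)
  expect_equal(back$survival$time, g$cohort$survival$time, tolerance = 1e-10)
  expect_identical(back$covariates$sex, g$cohort$covariates$sex)
})
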