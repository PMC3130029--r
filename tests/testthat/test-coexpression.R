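test_that("power adjacency follows the unsigned convention", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0.8, -0.5, 0.8, 1), 3, 3)
  a2 <- power_adjacency(r, 2)
  expect_equal(a2[1, 2], 0.25)
  expect_equal(a2[1, 3], 0.25)  # negative correlations enter unsigned
  expect_true(all(diag(a2) == 0))
  a_any <- power_adjacency(matrix(1, 2, 2), 7.3)
  expect_equal(a_any[1, 2], 1)
  # raising beta weakly decreases every off-diagonal entry
  a4 <- power_adjacency(r, 4)
  expect_true(all(a4[upper.tri(a4)] <= a2[upper.tri(a2)]))
  expect_error(power_adjacency(r, 0), "beta")
})

test_that("scale-free index is near 1 on an exact power law and errors on degenerate input", {
  k <- seq(5, 500, length.out = 10)
  degrees <- rep(k, times = round(1e5 * k^-2))
  sf <- scale_free_index(degrees)
  expect_gt(sf$fit_index, 0.99)
  expect_equal(sf$slope, -2, tolerance = 0.1)
  expect_error(scale_free_index(rep(7, 100)), "degenerate|bins")
})

test_that("beta selection returns the smallest qualifying power or a flagged fallback", {
  set.seed(101)
  # hub structure: genes loaded on a dominant factor with heterogeneous
  # loadings produce a heavy-tailed connectivity distribution
  n <- 120L
  g <- 150L
  load <- runif(g)^2
  f <- rnorm(n)
  x <- outer(load, f) + matrix(rnorm(g * n, 0, 0.6), g, n)
  cr <- cor(t(x))
  sel <- select_beta(cr, betas = seq(1, 12, 0.5), fit_min = 0.7)
  expect_true(3.5 %in% sel$scan$beta)   # the grid carries the classic choice
  if (sel$reached_fit_min) {
    earlier <- sel$scan$fit_index[sel$scan$beta < sel$beta]
    expect_true(all(is.na(earlier) | earlier < 0.7))
  }
  # degenerate equicorrelated input: the index is undefined at every beta,
  # so selection falls back with a flag
  fe <- rnorm(60)
  xe <- outer(rep(1, 40), fe) + matrix(rnorm(40 * 60, 0, 1e-4), 40, 60)
  seln <- select_beta(cor(t(xe)), fit_min = 0.7)
  expect_false(seln$reached_fit_min)
  expect_error(select_beta(cr, betas = c(3, 1)), "ascend")
})

test_that("module detection recovers implanted blocks and ignores noise", {
  cfg <- sim_config(n_pairs = 150L, n_genes = 300L, n_chromosomes = 3L,
                    snps_per_chromosome = 100L, n_an_modules = 2L,
                    module_size = 100L, n_tu_modules = 0L, n_hotspots = 0L,
                    cis_effect = 0, scnv_event_rate = 0,
                    survival_genes_an = 0L, survival_genes_tu = 0L)
  g <- generate_cohort(cfg)
  net <- coexpression_network(g$cohort$expression_an, beta = 6, tissue = "AN")
  expect_equal(net$n_modules, 2L)
  for (m in 1:2) {
    truth <- g$truth$an_modules[[m]]
    labels <- net$partition$module[net$partition$gene %in% truth]
    expect_gte(max(table(labels)) / length(truth), 0.95)
  }
  noise <- setdiff(g$cohort$gene_map$id, unlist(g$truth$an_modules))
  noise_labels <- net$partition$module[net$partition$gene %in% noise]
  expect_gte(mean(noise_labels == "grey"), 0.9)
  # color labels come from the size-ordered palette
  expect_setequal(names(net$sizes), c("turquoise", "blue"))

  # single all-correlated block collapses to one module
  set.seed(102)
  f <- rnorm(100)
  xb <- outer(rep(1, 60), f) + matrix(rnorm(60 * 100, 0, 0.4), 60, 100)
  rownames(xb) <- paste0("g", 1:60)
  one <- detect_modules(power_adjacency(cor(t(xb)), 6), min_size = 30L)
  expect_equal(one$n_modules, 1L)

  # gene order permutation leaves the partition invariant
  perm <- sample(nrow(g$cohort$expression_an))
  net_p <- coexpression_network(g$cohort$expression_an[perm, ], beta = 6)
  m1 <- setNames(net$partition$module, net$partition$gene)
  m2 <- setNames(net_p$partition$module, net_p$partition$gene)
  tab <- table(m1[names(m2)], m2)
  # same grouping up to label names: each label maps to exactly one label
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("TOM similarity is symmetric with unit diagonal and bounded", {
  set.seed(103)
  x <- matrix(rnorm(40 * 50), 40, 50)
  a <- power_adjacency(cor(t(x)), 4)
  tom <- tom_similarity(a)
  expect_equal(tom, t(tom), tolerance = 1e-12)
  expect_true(all(diag(tom) == 1))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("module overlap mapping flags matched partitions and not random ones", {
  genes <- sprintf("g%03d", 1:300)
  part <- structure(list(partition = data.frame(
    gene = genes, module = rep(c("turquoise", "blue", "grey"), each = 100),
    stringsAsFactors = FALSE)), class = "module_partition")
  self <- module_overlap_map(part, part)
  diag_rows <- self[self$set1 == "AN-turquoise" & self$set2 == "TU-turquoise", ]
  expect_equal(diag_rows$overlap, 100L)
  expect_equal(diag_rows$fold, 300 / 100, tolerance = 1e-12)
  expect_true(diag_rows$significant)

  set.seed(104)
  part2 <- part
  part2$partition$module <- sample(part$partition$module)
  rand <- module_overlap_map(part, part2)
  expect_lte(sum(rand$significant), 1L)
})
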