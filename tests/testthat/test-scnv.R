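toy_snp_map <- function(n, chrom = "chr1", spacing = 1e6) {
  data.frame(id = sprintf("s%03d", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * spacing, stringsAsFactors = FALSE)
}

test_that("logR smoothing windows are counted, placed and averaged correctly", {
  snp <- toy_snp_map(100L)
  x <- matrix(0.7, 100, 4, dimnames = list(snp$id, paste0("P", 1:4)))
  mk <- smooth_logr(x, snp, window = 40L, step = 20L)
  # floor((100 - 40) / 20) + 1 = 4 markers starting at SNPs 1, 21, 41, 61
  expect_equal(nrow(mk$values), 4L)
  expect_equal(mk$map$first_snp, c(1L, 21L, 41L, 61L))
  expect_true(all(mk$values == 0.7))
  expect_false(is.unsorted(mk$map$pos, strictly = TRUE))

  # windows never span chromosomes; short chromosomes yield none
  snp2 <- rbind(toy_snp_map(60L, "chr1"), toy_snp_map(45L, "chr2"),
                toy_snp_map(10L, "chr3"))
  x2 <- matrix(rnorm(115 * 3), 115, 3, dimnames = list(NULL, paste0("P", 1:3)))
  expect_message(mk2 <- smooth_logr(x2, snp2, 40L, 20L), "chr3")
  expect_equal(as.vector(table(mk2$map$chrom)[c("chr1", "chr2")]), c(2L, 1L))

  # linearity: smooth(aX + b) = a smooth(X) + b
  a <- 2.5
  b <- -0.3
  mka <- smooth_logr(a * x2 + b, snp2, 40L, 20L)
  expect_equal(mka$values, a * mk2$values + b, tolerance = 1e-12)

  # a segment covering a full window is recovered within noise
  set.seed(71)
  x3 <- matrix(rnorm(100 * 50, 0, 0.1), 100, 50,
               dimnames = list(snp$id, sprintf("P%02d", 1:50)))
  x3[21:60, 1L] <- x3[21:60, 1L] + 0.8
  mk3 <- smooth_logr(x3, snp, 40L, 20L)
  expect_equal(unname(mk3$values["m0002", 1L]), 0.8,
               tolerance = 4 * 0.1 / sqrt(40))
})

test_that("nearest cis marker respects distance and ties", {
  genes <- data.frame(id = c("gA", "gB", "gC"), chrom = "chr1",
                      pos = c(10e6, 30e6, 50e6), stringsAsFactors = FALSE)
  mk <- make_markers(matrix(rnorm(30), 3, 10,
                            dimnames = list(NULL, paste0("P", 1:10))),
                     chrom = "chr1", pos = c(9.9e6, 16e6, 52e6))
  cis <- nearest_cis_marker(genes, mk, max_distance = 5e6)
  expect_equal(cis$marker[cis$gene == "gA"], "m0001")   # 9.9 beats 16
  expect_true(is.na(cis$marker[cis$gene == "gB"]))      # 6 Mb away: none
  expect_equal(cis$marker[cis$gene == "gC"], "m0003")
  # equidistant: lower coordinate wins
  genes2 <- data.frame(id = "gT", chrom = "chr1", pos = 12.95e6,
                       stringsAsFactors = FALSE)
  expect_equal(nearest_cis_marker(genes2, mk, 5e6)$marker, "m0001")
  # gene on a chromosome without markers
  genes3 <- data.frame(id = "gZ", chrom = "chr9", pos = 1e6,
                       stringsAsFactors = FALSE)
  expect_true(is.na(nearest_cis_marker(genes3, mk)$marker))
})

test_that("gene-marker correlations match a per-pair oracle exactly", {
  set.seed(72)
  n <- 30L
  expr <- matrix(rnorm(15 * n), 15, n,
                 dimnames = list(paste0("g", 1:15), paste0("P", 1:n)))
  mk <- make_markers(matrix(rnorm(10 * n), 10, n,
                            dimnames = list(NULL, paste0("P", 1:n))),
                     chrom = rep(c("chr1", "chr2"), each = 5L))
  res <- gene_marker_correlations(expr, mk, r_cutoff = 0)
  for (i in c(1L, 7L, 15L)) {
    for (j in c(1L, 10L)) {
      o <- cor(expr[i, ], mk$values[j, ])
      got <- res$table$r[res$table$gene == paste0("g", i) &
                           res$table$marker == mk$map$marker[j]]
      expect_equal(got, o, tolerance = 1e-10)
    }
  }
  # deterministic trivial case: gene = 2 x marker
  expr2 <- matrix(2 * mk$values[1L, ], 1, n,
                  dimnames = list("gdup", paste0("P", 1:n)))
  res2 <- gene_marker_correlations(expr2, mk, r_cutoff = 0.3)
  expect_equal(res2$table$r[res2$table$marker == "m0001"], 1, tolerance = 1e-12)
  expect_error(gene_marker_correlations(expr[, 1:5], mk), "shared samples")
})

test_that("pairing permutation preserves marker structure and nulls the FDR", {
  set.seed(73)
  n <- 50L
  mk <- make_markers(matrix(rnorm(8 * n), 8, n,
                            dimnames = list(NULL, sprintf("P%02d", 1:n))),
                     chrom = rep(c("chr1", "chr2"), each = 4L))
  pm <- permute_marker_samples(mk, 5L)
  expect_equal(cor(t(pm$values)), cor(t(mk$values)), tolerance = 1e-12)
  expect_false(identical(pm$values, mk$values))

  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(paste0("g", 1:40), sprintf("P%02d", 1:n)))
  out <- pairing_permutation_fdr(expr, mk, r_cutoff = 0.28, n_perm = 5L,
                                 seed = 2L)
  expect_gte(out$fdr, 0.3)  # independent data: permuted counts match real
})

test_that("hotspot detection applies the count and per-chromosome rules", {
  # constructed correlation table: m1/m2 share chr1, m3 on chr2
  genes <- data.frame(id = sprintf("g%03d", 1:700), chrom = "chr9",
                      pos = seq_len(700) * 1e5, stringsAsFactors = FALSE)
  mk <- make_markers(matrix(0, 3, 10, dimnames = list(NULL, paste0("P", 1:10))),
                     chrom = c("chr1", "chr1", "chr2"))
  tab <- rbind(
    data.frame(gene = genes$id[1:600], marker = "m0001", r = 0.5),
    data.frame(gene = genes$id[1:550], marker = "m0002", r = 0.5),
    data.frame(gene = genes$id[1:10], marker = "m0003", r = 0.5))
  cr <- list(table = tab, r_cutoff = 0.3)
  hs <- detect_hotspots(cr, mk, genes, min_genes = 500L)
  expect_equal(hs$hotspots$marker, "m0001")  # top marker per chromosome only
  expect_equal(hs$hotspots$n_genes, 600L)
  expect_setequal(hs$regulons[["m0001"]], genes$id[1:600])
  # nothing above the cutoff: empty set
  hs0 <- detect_hotspots(cr, mk, genes, min_genes = 1000L)
  expect_equal(nrow(hs0$hotspots), 0L)
  # negative correlations only count in absolute mode
  tab_neg <- transform(tab, r = -r)
  hs_neg <- detect_hotspots(list(table = tab_neg), mk, genes, min_genes = 500L)
  expect_equal(nrow(hs_neg$hotspots), 0L)
  hs_abs <- detect_hotspots(list(table = tab_neg), mk, genes,
                            min_genes = 500L, use_abs = TRUE)
  expect_equal(hs_abs$hotspots$marker, "m0001")
})

test_that("stepwise selection recovers known variance decompositions", {
  set.seed(74)
  n <- 600L
  m1 <- rnorm(n)
  m2 <- rnorm(n)
  mk <- make_markers(rbind(m1, m2, rnorm(n)),
                     chrom = c("chr1", "chr2", "chr3"))
  colnames(mk$values) <- sprintf("P%03d", 1:n)

  # exact dosage: one marker, R^2 = 1
  v1 <- stepwise_variance(3 * m1, mk)
  expect_equal(nrow(v1$selected), 1L)
  expect_equal(v1$selected$marker, "m0001")
  expect_equal(v1$adj_r2, 1, tolerance = 1e-9)

  # pure noise: empty model, R^2 reported as 0
  v0 <- stepwise_variance(rnorm(n), mk)
  expect_equal(nrow(v0$selected), 0L)
  expect_equal(v0$adj_r2, 0)

  # two independent markers on distinct chromosomes, population R^2 = 0.605
  y <- 0.55 * m1 + 0.55 * m2 + rnorm(n, 0, sqrt(0.4))
  v2 <- stepwise_variance(y, mk)
  expect_setequal(v2$selected$marker, c("m0001", "m0002"))
  expect_lt(abs(v2$adj_r2 - 0.605), 0.05)
  # RMSE trace strictly decreases
  expect_true(all(diff(v2$rmse_trace) < 0))
  expect_error(stepwise_variance(rnorm(10), mk), "20 samples")
})

test_that("variance summary conserves counts across tables", {
  g <- generate_cohort(small_config(cis_effect = 0.6))
  mk <- smooth_logr(g$cohort$logr_tu, g$cohort$snp_map)
  vm <- stepwise_variance_all(g$cohort$expression_tu, mk)
  cis <- nearest_cis_marker(g$cohort$gene_map, mk)
  pm <- permute_marker_samples(mk, 3L)
  vp <- stepwise_variance_all(g$cohort$expression_tu, pm)
  vs <- variance_summary(vm, cis, g$cohort$expression_tu, mk,
                         permuted_models = vp, permuted_markers = pm)
  expect_equal(sum(vs$marker_counts), sum(vm$summary$n_markers > 0))
  # counts are monotone non-increasing in the cutoff
  expect_true(all(diff(vs$r2_counts$trans_cis) <= 0))
  expect_true(all(vs$r2_counts$cis <= vs$r2_counts$trans_cis))
  # all-zero models yield zero counts
  vm0 <- vm
  vm0$summary$adj_r2 <- 0
  vs0 <- variance_summary(vm0, cis, g$cohort$expression_tu, mk)
  expect_true(all(vs0$r2_counts$trans_cis == 0L))
})
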