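test_that("Fisher Z and heterogeneity Q match closed forms", {
  expect_equal(fisher_z(0, 10)$z, 0)
  expect_equal(fisher_z(0.8, 10)$z, 0.5 * log(9), tolerance = 1e-12)
  expect_equal(fisher_z(0.5, 103)$sd, 0.1, tolerance = 1e-12)
  expect_error(fisher_z(1, 10), "< 1")
  expect_error(fisher_z(0.5, 3), "exceed 3")

  # homogeneity: Q = 0, p = 1
  q0 <- heterogeneity_q(0.6, 50, 0.6, 80)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  # two-group closed form: r_an = 0.8, r_tu = 0, n = 200 both
  q1 <- heterogeneity_q(0.8, 200, 0, 200)
  expect_equal(q1$Q, (197^2 / 394) * (0.5 * log(9))^2, tolerance = 1e-12)
  expect_equal(q1$Q, 118.9, tolerance = 0.001)
  expect_gt(q1$Q, 80)

  # a pair landing exactly at the chi-square(1) 95th percentile has p = 0.05
  z_at <- sqrt(3.841459 / (197^2 / 394))
  r_at <- tanh(z_at)
  q2 <- heterogeneity_q(r_at, 200, 0, 200)
  expect_equal(q2$Q, 3.841459, tolerance = 1e-6)
  expect_equal(q2$p, 0.05, tolerance = 1e-6)
})

test_that("the blocked scan equals the brute-force pairwise oracle", {
  set.seed(61)
  g <- 20L
  xan <- matrix(rnorm(g * 15), g, 15, dimnames = list(paste0("g", 1:g), NULL))
  xtu <- matrix(rnorm(g * 12), g, 12, dimnames = list(paste0("g", 1:g), NULL))
  oracle <- brute_force_diffcorr(xan, xtu)
  # force blocking with a tiny block size
  fit <- diffcorr_scan(xan, xtu, meta_config(q_threshold = 0.5,
                                             block_size = 7L))
  expect_equal(nrow(fit$pairs), sum(oracle$q > 0.5))
  key_fit <- paste(fit$pairs$gene_i, fit$pairs$gene_j)
  o <- oracle[oracle$q > 0.5, ]
  key_o <- paste0("g", o$i, " g", o$j)
  expect_setequal(key_fit, key_o)
  m <- match(key_o, key_fit)
  expect_equal(fit$pairs$q[m], o$q, tolerance = 1e-10)
  expect_equal(fit$pairs$r_an[m], o$r_an, tolerance = 1e-10)
  expect_equal(fit$pairs$r_tu[m], o$r_tu, tolerance = 1e-10)
})

test_that("scan invariants hold: self-comparison, degree conservation, monotone invariance", {
  set.seed(62)
  x <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(paste0("g", 1:30), NULL))
  self <- diffcorr_scan(x, x, meta_config(q_threshold = 1e-9))
  expect_equal(self$n_retained, 0L)

  y <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(paste0("g", 1:30), NULL))
  fit <- diffcorr_scan(x, y, meta_config(q_threshold = 2))
  expect_equal(sum(fit$genes$diff_connection_count), 2L * fit$n_retained)
  expect_equal(fit$genes$goc_count + fit$genes$loc_count,
               fit$genes$diff_connection_count)

  # rank correlation makes Q invariant to monotone transforms
  fit2 <- diffcorr_scan(exp(x), y^3, meta_config(q_threshold = 2))
  expect_equal(fit$pairs$q, fit2$pairs$q, tolerance = 1e-10)

  # tissue-order symmetry of Q
  fit_rev <- diffcorr_scan(y, x, meta_config(q_threshold = 2))
  expect_equal(sort(fit_rev$pairs$q), sort(fit$pairs$q), tolerance = 1e-10)

  expect_error(diffcorr_scan(x, y[1:10, ]), "mismatched")
})

test_that("null Q follows chi-square(1) at modest n", {
  set.seed(63)
  npair <- 4000L
  n <- 60L
  # both tissues share the generating correlation 0.5
  mk <- function() {
    a <- matrix(rnorm(npair * n), npair)
    b <- 0.5 * a + sqrt(0.75) * matrix(rnorm(npair * n), npair)
    list(a = a, b = b)
  }
  t1 <- mk()
  t2 <- mk()
  r1 <- row_spearman(t1$a, t1$b)
  r2 <- row_spearman(t2$a, t2$b)
  q <- heterogeneity_q(r1, n, r2, n)
  expect_lt(abs(mean(q$Q > qchisq(0.95, 1)) - 0.05), 0.02)
})

test_that("connectivity classification applies the strict 90% rule", {
  fake <- list(genes = data.frame(
    gene = c("a", "b", "c", "d"),
    diff_connection_count = c(10L, 10L, 0L, 10L),
    goc_count = c(10L, 9L, 0L, 0L),
    loc_count = c(0L, 1L, 0L, 10L), stringsAsFactors = FALSE))
  cls <- classify_connectivity(fake, 0.90)
  expect_equal(cls$class, c("GOC", "mixed", "none", "LOC"))
})

test_that("degree distribution fitting recovers a power law", {
  k <- 1:50
  degrees <- rep(k, times = round(1e4 * k^-2))
  fit <- degree_power_law(degrees)
  expect_equal(fit$exponent, -2, tolerance = 0.02)
  expect_gt(fit$fit_index, 0.999)
  # uniform counts: flat line in log-log
  flat <- rep(1:20, each = 5)
  expect_lt(degree_power_law(flat)$fit_index, 0.05)
  expect_error(degree_power_law(rep(c(1, 2), 10)), "5 distinct")
})

test_that("split-half control yields disjoint exhaustive halves and few pairs", {
  g <- generate_cohort(small_config())
  ctrl <- split_half_control(g$cohort$expression_an, meta_config())
  expect_length(intersect(ctrl$half1, ctrl$half2), 0L)
  expect_setequal(c(ctrl$half1, ctrl$half2),
                  seq_len(ncol(g$cohort$expression_an)))
  expect_lt(ctrl$fit$n_retained, 10L)
  ctrl2 <- split_half_control(g$cohort$expression_an, meta_config())
  expect_identical(ctrl$half1, ctrl2$half1)
  expect_error(split_half_control(g$cohort$expression_an[, 1:6]), "8 AN")
})

test_that("label-permutation FDR is reproducible and near 1 under the null", {
  set.seed(64)
  x <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(paste0("g", 1:60), NULL))
  y <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(paste0("g", 1:60), NULL))
  cfg <- meta_config(n_label_permutations = 2L)
  fdr <- label_permutation_fdr(x, y, cfg, thresholds = qchisq(0.95, 1))
  expect_gt(fdr$fdr[1L], 0.5)
  fdr2 <- label_permutation_fdr(x, y, cfg, thresholds = qchisq(0.95, 1))
  expect_identical(fdr, fdr2)
})
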