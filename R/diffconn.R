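#' Configuration for the differential-correlation meta-analysis
#'
#' @param q_threshold Q statistic retention cutoff (Q0).
#' @param pair_p_threshold per-pair Bonferroni reporting threshold.
#' @param goc_loc_fraction strict fraction above which a gene's differential
#'   interactions classify it as gain (GOC) or loss (LOC) of connectivity.
#' @param correlation_method `"spearman"` (rank, midranks for ties; default)
#'   or `"pearson"`.
#' @param n_label_permutations label permutations for the empirical FDR.
#' @param block_size gene block size for the pairwise scan (memory bound).
#' @param seed seed for permutations and sample splits.
#' @return object of class `meta_config`.
#' @export
meta_config <- function(q_threshold = 80, pair_p_threshold = 7e-11,
                        goc_loc_fraction = 0.90,
                        correlation_method = c("spearman", "pearson"),
                        n_label_permutations = 1L, block_size = 1000L,
                        seed = 1L) {
  if (q_threshold <= 0) stop("q_threshold must be > 0", call. = FALSE)
  if (goc_loc_fraction <= 0.5 || goc_loc_fraction >= 1) {
    stop("goc_loc_fraction must lie in (0.5, 1)", call. = FALSE)
  }
  structure(list(q_threshold = q_threshold,
                 pair_p_threshold = pair_p_threshold,
                 goc_loc_fraction = goc_loc_fraction,
                 correlation_method = match.arg(correlation_method),
                 n_label_permutations = as.integer(n_label_permutations),
                 block_size = as.integer(block_size),
                 seed = as.integer(seed)),
            class = "meta_config")
}

#' Fisher Z transform of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))` with standard deviation
#' `1 / sqrt(n - 3)`.
#'
#' @param r correlation coefficient(s), strictly inside (-1, 1).
#' @param n sample count(s), must exceed 3.
#' @return list with `z` and `sd`.
#' @export
fisher_z <- function(r, n) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  if (any(n <= 3)) stop("n must exceed 3", call. = FALSE)
  list(z = 0.5 * log((1 + r) / (1 - r)), sd = 1 / sqrt(n - 3))
}

#' Heterogeneity Q statistic for a gene pair across two tissues
#'
#' With weights `w_t = n_t - 3` and weighted mean Z, the statistic is
#' `Q = sum w_t (z_t - zbar)^2`, which for two groups reduces to
#' `(w1 w2 / (w1 + w2)) (z1 - z2)^2` and follows chi-square with 1 df under
#' homogeneity. Vectorized over pairs.
#'
#' @param r_an,r_tu correlations in each tissue.
#' @param n_an,n_tu sample counts per tissue.
#' @return list with `Q` and upper-tail `p` (chi-square, 1 df).
#' @export
heterogeneity_q <- function(r_an, n_an, r_tu, n_tu) {
  z1 <- fisher_z(r_an, n_an)$z
  z2 <- fisher_z(r_tu, n_tu)$z
  w1 <- n_an - 3
  w2 <- n_tu - 3
  q <- (w1 * w2 / (w1 + w2)) * (z1 - z2)^2
  p <- stats::pchisq(q, df = 1, lower.tail = FALSE)
  list(Q = q, p = pmax(p, .Machine$double.xmin))
}

# row-standardize so tcrossprod gives the correlation matrix; rank rows first
# for the Spearman method
corr_basis <- function(x, method) {
  x <- adj_matrix(x)
  if (method == "spearman") x <- rank_rows(x)
  x <- x - rowMeans(x)
  s <- sqrt(rowSums(x^2))
  s[s == 0] <- 1
  x / s
}

#' All-pairs differential-correlation scan between tissues
#'
#' Computes the per-tissue correlation for every unordered gene pair, the
#' Fisher-Z heterogeneity Q and its chi-square p, retains pairs with
#' `Q > q_threshold`, and tallies per-gene differential connections split by
#' direction (a retained pair is "stronger in AN" iff `|r_an| >= |r_tu|`).
#' The scan runs over gene blocks so memory stays bounded.
#'
#' @param adj_an,adj_tu [robust_covariate_adjust()] results (or bare gene x
#'   sample matrices) with identical gene rows.
#' @param config a [meta_config()].
#' @return object of class `diffconn_fit`: `pairs` (gene_i, gene_j, r_an,
#'   r_tu, q, p, direction), `genes` (diff_connection_count, goc_count,
#'   loc_count, class), counts and the configuration.
#' @export
diffcorr_scan <- function(adj_an, adj_tu, config = meta_config()) {
  xan <- adj_matrix(adj_an)
  xtu <- adj_matrix(adj_tu)
  if (!identical(rownames(xan), rownames(xtu))) {
    stop("tissue matrices have mismatched genes", call. = FALSE)
  }
  n_an <- ncol(xan)
  n_tu <- ncol(xtu)
  if (n_an <= 3 || n_tu <= 3) stop("need > 3 samples per tissue", call. = FALSE)
  g <- nrow(xan)
  ids <- rownames(xan) %||% as.character(seq_len(g))
  zan <- corr_basis(xan, config$correlation_method)
  ztu <- corr_basis(xtu, config$correlation_method)
  w1 <- n_an - 3
  w2 <- n_tu - 3
  wfac <- w1 * w2 / (w1 + w2)
  q0 <- config$q_threshold
  bs <- config$block_size
  starts <- seq(1L, g, by = bs)
  pairs <- list()
  deg <- integer(g)
  goc <- integer(g)
  for (bi in seq_along(starts)) {
    i_idx <- starts[bi]:min(starts[bi] + bs - 1L, g)
    for (bj in bi:length(starts)) {
      j_idx <- starts[bj]:min(starts[bj] + bs - 1L, g)
      r1 <- clamp_r(tcrossprod(zan[i_idx, , drop = FALSE],
                               zan[j_idx, , drop = FALSE]))
      r2 <- clamp_r(tcrossprod(ztu[i_idx, , drop = FALSE],
                               ztu[j_idx, , drop = FALSE]))
      q <- wfac * (atanh(r1) - atanh(r2))^2
      keep <- q > q0
      if (bi == bj) keep[lower.tri(keep, diag = TRUE)] <- FALSE
      hits <- which(keep, arr.ind = TRUE)
      if (nrow(hits)) {
        gi <- i_idx[hits[, 1L]]
        gj <- j_idx[hits[, 2L]]
        ra <- r1[hits]
        rt <- r2[hits]
        qq <- q[hits]
        stronger_tu <- abs(rt) > abs(ra)
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_i = ids[gi], gene_j = ids[gj], r_an = ra, r_tu = rt, q = qq,
          p = pmax(stats::pchisq(qq, 1, lower.tail = FALSE),
                   .Machine$double.xmin),
          direction = ifelse(stronger_tu, "stronger-in-TU", "stronger-in-AN"),
          stringsAsFactors = FALSE)
        deg <- deg + tabulate(c(gi, gj), nbins = g)
        goc <- goc + tabulate(c(gi[stronger_tu], gj[stronger_tu]), nbins = g)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_i = character(), gene_j = character(), r_an = numeric(),
               r_tu = numeric(), q = numeric(), p = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  genes <- data.frame(gene = ids, diff_connection_count = deg,
                      goc_count = goc, loc_count = deg - goc,
                      stringsAsFactors = FALSE)
  fit <- structure(list(pairs = pairs, genes = genes, config = config,
                        n_an = n_an, n_tu = n_tu,
                        n_pairs_tested = g * (g - 1) / 2,
                        n_retained = nrow(pairs)),
                   class = "diffconn_fit")
  fit$genes$class <- classify_connectivity(fit, config$goc_loc_fraction)$class
  fit
}

#' @export
print.diffconn_fit <- function(x, ...) {
  cat("Differential-connectivity scan (heterogeneity Q meta-analysis)\n")
  cat(sprintf("  %d genes, %s pairs tested, n = %d (AN) / %d (TU)\n",
              nrow(x$genes), format(x$n_pairs_tested, big.mark = ","),
              x$n_an, x$n_tu))
  cat(sprintf("  %d pairs retained at Q > %.4g (%d stronger in AN, %d in TU)\n",
              x$n_retained, x$config$q_threshold,
              sum(x$pairs$direction == "stronger-in-AN"),
              sum(x$pairs$direction == "stronger-in-TU")))
  cls <- table(factor(x$genes$class, c("GOC", "LOC", "mixed", "none")))
  cat(sprintf("  gene classes: %d GOC, %d LOC, %d mixed, %d none\n",
              cls["GOC"], cls["LOC"], cls["mixed"], cls["none"]))
  invisible(x)
}

#' @export
summary.diffconn_fit <- function(object, ...) {
  print(object)
  if (object$n_retained > 0) {
    cat("  top pairs by Q:\n")
    top <- utils::head(object$pairs[order(-object$pairs$q), ], 5L)
    print(top, row.names = FALSE)
  }
  invisible(object)
}

# internal: counts of pairs with Q >= each threshold (upper triangle only)
q_tail_counts <- function(zan, ztu, wfac, thresholds, block_size) {
  g <- nrow(zan)
  starts <- seq(1L, g, by = block_size)
  counts <- numeric(length(thresholds))
  for (bi in seq_along(starts)) {
    i_idx <- starts[bi]:min(starts[bi] + block_size - 1L, g)
    for (bj in bi:length(starts)) {
      j_idx <- starts[bj]:min(starts[bj] + block_size - 1L, g)
      r1 <- clamp_r(tcrossprod(zan[i_idx, , drop = FALSE],
                               zan[j_idx, , drop = FALSE]))
      r2 <- clamp_r(tcrossprod(ztu[i_idx, , drop = FALSE],
                               ztu[j_idx, , drop = FALSE]))
      q <- wfac * (atanh(r1) - atanh(r2))^2
      if (bi == bj) q[lower.tri(q, diag = TRUE)] <- -Inf
      for (t in seq_along(thresholds)) {
        counts[t] <- counts[t] + sum(q >= thresholds[t])
      }
    }
  }
  counts
}

#' Label-permutation false discovery rate for the Q scan
#'
#' Reassigns AN/TU labels at random within each matched pair (each patient's
#' two samples swap tissues with probability one half), repeats the scan, and
#' reports `FDR(t) = mean permuted count at Q >= t / real count at Q >= t`,
#' capped at 1. A zero real count yields FDR 1 with a flag.
#'
#' @param adj_an,adj_tu adjusted expression (shared genes; columns are
#'   matched by position across tissues).
#' @param config a [meta_config()] (`n_label_permutations`, `seed`).
#' @param thresholds Q thresholds for the curve; defaults to a chi-square
#'   quantile grid plus the configured Q0.
#' @return data frame: threshold, real_count, mean permuted count, fdr, flag.
#' @export
label_permutation_fdr <- function(adj_an, adj_tu, config = meta_config(),
                                  thresholds = NULL) {
  xan <- adj_matrix(adj_an)
  xtu <- adj_matrix(adj_tu)
  if (!identical(rownames(xan), rownames(xtu))) {
    stop("tissue matrices have mismatched genes", call. = FALSE)
  }
  if (ncol(xan) != ncol(xtu)) {
    stop("label permutation requires matched samples", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(stats::qchisq(c(0.95, 0.99, 0.999), 1),
                                10, 20, 40, 60, config$q_threshold, 100)))
  }
  w1 <- ncol(xan) - 3
  w2 <- ncol(xtu) - 3
  wfac <- w1 * w2 / (w1 + w2)
  zan <- corr_basis(xan, config$correlation_method)
  ztu <- corr_basis(xtu, config$correlation_method)
  real <- q_tail_counts(zan, ztu, wfac, thresholds, config$block_size)
  perm <- matrix(0, config$n_label_permutations, length(thresholds))
  with_substream(config$seed, "label_permutation", {
    for (p in seq_len(config$n_label_permutations)) {
      swap <- stats::runif(ncol(xan)) < 0.5
      pan <- xan
      ptu <- xtu
      pan[, swap] <- xtu[, swap]
      ptu[, swap] <- xan[, swap]
      perm[p, ] <- q_tail_counts(corr_basis(pan, config$correlation_method),
                                 corr_basis(ptu, config$correlation_method),
                                 wfac, thresholds, config$block_size)
    }
  })
  mean_perm <- colMeans(perm)
  fdr <- ifelse(real > 0, pmin(mean_perm / real, 1), 1)
  data.frame(threshold = thresholds, real_count = real,
             mean_perm_count = mean_perm, fdr = fdr,
             no_real_discoveries = real == 0)
}

#' AN-versus-AN split-half control scan
#'
#' Splits the AN samples into two seeded random halves (the larger half gets
#' the extra sample when the count is odd) and runs the differential scan
#' between them; under tissue homogeneity essentially no pairs should be
#' retained, in contrast to the AN-versus-TU scan.
#'
#' @param adj_an adjusted AN expression (>= 8 samples).
#' @param config a [meta_config()].
#' @return list with the `diffconn_fit` of the half-vs-half scan and the two
#'   sample index sets.
#' @export
split_half_control <- function(adj_an, config = meta_config()) {
  x <- adj_matrix(adj_an)
  n <- ncol(x)
  if (n < 8L) stop("need at least 8 AN samples", call. = FALSE)
  with_substream(config$seed, "split_half", {
    half1 <- sort(sample.int(n, ceiling(n / 2)))
    half2 <- setdiff(seq_len(n), half1)
    fit <- diffcorr_scan(x[, half1, drop = FALSE], x[, half2, drop = FALSE],
                         config)
    list(fit = fit, half1 = half1, half2 = half2)
  })
}

#' Classify genes by direction of their differential connections
#'
#' A gene is GOC (gain of connectivity) when strictly more than `fraction`
#' of its retained differential pairs are stronger in TU, LOC when strictly
#' more than `fraction` are stronger in AN, `none` with zero differential
#' connections, `mixed` otherwise.
#'
#' @param result a [diffcorr_scan()] fit.
#' @param fraction classification fraction (strict inequality).
#' @return data frame gene/class.
#' @export
classify_connectivity <- function(result, fraction = 0.90) {
  g <- result$genes
  frac_goc <- ifelse(g$diff_connection_count > 0,
                     g$goc_count / g$diff_connection_count, NA_real_)
  class <- ifelse(g$diff_connection_count == 0, "none",
                  ifelse(frac_goc > fraction, "GOC",
                         ifelse(1 - frac_goc > fraction, "LOC", "mixed")))
  data.frame(gene = g$gene, class = class, stringsAsFactors = FALSE)
}

#' Power-law fit to the differential-connection degree distribution
#'
#' Regresses `log10(count)` on `log10(degree)` over observed degrees >= 1;
#' the slope estimates the power-law exponent and R-squared is the fit index.
#'
#' @param result a [diffcorr_scan()] fit, or a numeric vector of per-gene
#'   degrees.
#' @return list with `exponent` (slope) and `fit_index` (R-squared).
#' @export
degree_power_law <- function(result) {
  degrees <- if (inherits(result, "diffconn_fit"))
    result$genes$diff_connection_count else as.numeric(result)
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  if (length(tab) < 5L) stop("need at least 5 distinct degree values",
                             call. = FALSE)
  k <- as.numeric(names(tab))
  y <- log10(as.numeric(tab))
  if (stats::sd(y) < 1e-12) {
    # flat count profile: no decay to fit
    return(list(exponent = 0, fit_index = 0))
  }
  fit <- stats::lm(y ~ log10(k))
  list(exponent = unname(stats::coef(fit)[2L]),
       fit_index = summary(fit)$r.squared)
}

#' Count gene pairs correlated in either tissue
#'
#' Census of pairs whose per-tissue correlation p-value beats a threshold in
#' at least one tissue (default: 0.05 Bonferroni-adjusted over all pairs);
#' the usual denominator when quoting the fraction of differentially
#' connected pairs.
#'
#' @param adj_an,adj_tu adjusted expression matrices with shared genes.
#' @param p_threshold per-pair threshold; default `0.05 / choose(g, 2)`.
#' @param config a [meta_config()] (correlation method, block size).
#' @return number of pairs correlated in either tissue.
#' @export
count_correlated_pairs <- function(adj_an, adj_tu, p_threshold = NULL,
                                   config = meta_config()) {
  xan <- adj_matrix(adj_an)
  xtu <- adj_matrix(adj_tu)
  g <- nrow(xan)
  if (is.null(p_threshold)) p_threshold <- 0.05 / choose(g, 2)
  # invert the correlation t-test: |r| cutoff at the requested p
  r_cut <- function(n) {
    tq <- stats::qt(p_threshold / 2, df = n - 2, lower.tail = FALSE)
    tq / sqrt(n - 2 + tq^2)
  }
  cut_an <- r_cut(ncol(xan))
  cut_tu <- r_cut(ncol(xtu))
  zan <- corr_basis(xan, config$correlation_method)
  ztu <- corr_basis(xtu, config$correlation_method)
  bs <- config$block_size
  starts <- seq(1L, g, by = bs)
  total <- 0
  for (bi in seq_along(starts)) {
    i_idx <- starts[bi]:min(starts[bi] + bs - 1L, g)
    for (bj in bi:length(starts)) {
      j_idx <- starts[bj]:min(starts[bj] + bs - 1L, g)
      r1 <- tcrossprod(zan[i_idx, , drop = FALSE], zan[j_idx, , drop = FALSE])
      r2 <- tcrossprod(ztu[i_idx, , drop = FALSE], ztu[j_idx, , drop = FALSE])
      hit <- abs(r1) >= cut_an | abs(r2) >= cut_tu
      if (bi == bj) hit[lower.tri(hit, diag = TRUE)] <- FALSE
      total <- total + sum(hit)
    }
  }
  total
}
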