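# shared fixtures: all built in code at test time

# a small, fast cohort configuration for unit tests
small_config <- function(...) {
  defaults <- list(n_pairs = 60L, n_genes = 300L, n_chromosomes = 3L,
                   snps_per_chromosome = 100L, n_an_modules = 2L,
                   n_tu_modules = 1L, module_size = 30L, n_hotspots = 1L,
                   hotspot_regulon_size = 40L, survival_genes_an = 1L,
                   survival_genes_tu = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# independent Spearman row-correlation oracle (rank + product moment)
row_spearman <- function(A, B) {
  A <- t(apply(A, 1L, rank))
  B <- t(apply(B, 1L, rank))
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  rowSums(A * B) / sqrt(rowSums(A^2) * rowSums(B^2))
}

# brute-force differential-correlation oracle: per-pair loop with cor()
# and the two-group closed form, fully independent of the blocked scan
brute_force_diffcorr <- function(xan, xtu, method = "spearman") {
  g <- nrow(xan)
  n1 <- ncol(xan)
  n2 <- ncol(xtu)
  out <- list()
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      r1 <- cor(xan[i, ], xan[j, ], method = method)
      r2 <- cor(xtu[i, ], xtu[j, ], method = method)
      z1 <- 0.5 * log((1 + r1) / (1 - r1))
      z2 <- 0.5 * log((1 + r2) / (1 - r2))
      w1 <- n1 - 3
      w2 <- n2 - 3
      q <- (w1 * w2 / (w1 + w2)) * (z1 - z2)^2
      out[[length(out) + 1L]] <- data.frame(i = i, j = j, r_an = r1,
                                            r_tu = r2, q = q)
    }
  }
  do.call(rbind, out)
}

# hand-built marker set on a given number of chromosomes
make_markers <- function(values, chrom, pos = NULL) {
  n <- nrow(values)
  if (is.null(pos)) pos <- seq_len(n) * 1e6
  map <- data.frame(marker = sprintf("m%04d", seq_len(n)), chrom = chrom,
                    pos = pos, first_snp = NA_integer_,
                    last_snp = NA_integer_, stringsAsFactors = FALSE)
  rownames(values) <- map$marker
  structure(list(values = values, map = map, window = 40L, step = 20L),
            class = "scnv_markers")
}

# exact hypergeometric upper-tail oracle by direct summation of choose()
hyper_tail_oracle <- function(k, n_a, n_b, n_u) {
  j <- k:min(n_a, n_b)
  sum(exp(lchoose(n_b, j) + lchoose(n_u - n_b, n_a - j) - lchoose(n_u, n_a)))
}
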