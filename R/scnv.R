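#' Smooth SNP logR ratios into sCNV markers
#'
#' Slides a `window`-SNP averaging window in steps of `step` SNPs within each
#' chromosome (never across a chromosome boundary); each marker is the mean
#' logR of its window per sample, positioned at the midpoint of the first and
#' last contributing SNPs. Chromosomes with fewer SNPs than `window` yield no
#' markers.
#'
#' @param logr SNP x sample matrix, rows sorted by (chromosome, position).
#' @param snp_map data frame `id`, `chrom`, `pos` aligned with `logr` rows.
#' @param window,step SNP counts (defaults 40 and 20).
#' @return object of class `scnv_markers`: `values` (marker x sample matrix)
#'   and `map` (marker, chrom, center pos, first/last SNP row), with window
#'   and step recorded.
#' @export
smooth_logr <- function(logr, snp_map, window = 40L, step = 20L) {
  logr <- as.matrix(logr)
  if (nrow(logr) != nrow(snp_map)) {
    stop("logr rows and snp_map rows differ", call. = FALSE)
  }
  ord_ok <- all(unlist(tapply(snp_map$pos, snp_map$chrom,
                              function(p) !is.unsorted(p, strictly = TRUE))))
  if (!ord_ok) stop("SNPs must be sorted by (chromosome, position)",
                    call. = FALSE)
  vals <- list()
  map <- list()
  for (ch in unique(snp_map$chrom)) {
    rows <- which(snp_map$chrom == ch)
    m <- length(rows)
    if (m < window) {
      message(sprintf("chromosome %s has %d < %d SNPs; no markers", ch, m,
                      window))
      next
    }
    starts <- seq(1L, m - window + 1L, by = step)
    for (s in starts) {
      idx <- rows[s:(s + window - 1L)]
      vals[[length(vals) + 1L]] <- colMeans(logr[idx, , drop = FALSE])
      map[[length(map) + 1L]] <- data.frame(
        marker = NA_character_, chrom = ch,
        pos = floor((snp_map$pos[idx[1L]] + snp_map$pos[idx[window]]) / 2),
        first_snp = idx[1L], last_snp = idx[window], stringsAsFactors = FALSE)
    }
  }
  if (!length(vals)) stop("no chromosome held enough SNPs for one window",
                          call. = FALSE)
  values <- do.call(rbind, vals)
  map <- do.call(rbind, map)
  map$marker <- sprintf("m%04d", seq_len(nrow(map)))
  rownames(values) <- map$marker
  structure(list(values = values, map = map, window = as.integer(window),
                 step = as.integer(step)), class = "scnv_markers")
}

#' @export
print.scnv_markers <- function(x, ...) {
  cat(sprintf("sCNV markers: %d markers x %d samples (%d-SNP window, %d-SNP step)\n",
              nrow(x$values), ncol(x$values), x$window, x$step))
  invisible(x)
}

#' Nearest cis marker per gene
#'
#' For each gene, the marker on the same chromosome minimizing the distance
#' between gene position and marker center, retained only when within
#' `max_distance`; equidistant candidates resolve to the lower-coordinate
#' marker.
#'
#' @param gene_map data frame `id`, `chrom`, `pos`.
#' @param markers a [smooth_logr()] result.
#' @param max_distance cis window in bp (default 5 Mb).
#' @return data frame gene, marker (NA when none qualifies), distance.
#' @export
nearest_cis_marker <- function(gene_map, markers, max_distance = 5e6) {
  stopifnot(inherits(markers, "scnv_markers"))
  out <- data.frame(gene = gene_map$id, marker = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(gene_map$chrom)) {
    mrows <- which(markers$map$chrom == ch)
    if (!length(mrows)) next
    mpos <- markers$map$pos[mrows]
    gi <- which(gene_map$chrom == ch)
    near <- findInterval(gene_map$pos[gi], mpos)
    for (k in seq_along(gi)) {
      lo <- max(near[k], 1L)
      hi <- min(near[k] + 1L, length(mpos))
      cand <- lo:hi
      d <- abs(mpos[cand] - gene_map$pos[gi[k]])
      best <- cand[which.min(d)]  # which.min takes the first = lower coord
      if (min(d) <= max_distance) {
        out$marker[gi[k]] <- markers$map$marker[mrows[best]]
        out$distance[gi[k]] <- min(d)
      }
    }
  }
  out
}

#' Genome-wide gene-by-marker correlation table
#'
#' Pearson correlation between every adjusted gene trait and every smoothed
#' marker; entries with `|r| >= r_cutoff` are retained in sparse form, and
#' per-marker counts of positive and negative trans associations (gene and
#' marker on different chromosomes) are tallied.
#'
#' @param adj_expression adjusted expression (gene x sample).
#' @param markers a [smooth_logr()] result sharing the samples.
#' @param r_cutoff retention cutoff on `|r|`.
#' @param gene_map optional gene map (`id`, `chrom`); needed for trans counts.
#' @return list with `table` (gene, marker, r), `marker_counts` (marker,
#'   n_pos_trans, n_neg_trans) and the cutoff.
#' @export
gene_marker_correlations <- function(adj_expression, markers, r_cutoff = 0.3,
                                     gene_map = NULL) {
  x <- adj_matrix(adj_expression)
  stopifnot(inherits(markers, "scnv_markers"))
  shared <- intersect(colnames(x), colnames(markers$values))
  if (length(shared) < 10L) stop("fewer than 10 shared samples", call. = FALSE)
  r <- stats::cor(t(x[, shared, drop = FALSE]),
                  t(markers$values[, shared, drop = FALSE]))
  hits <- which(abs(r) >= r_cutoff, arr.ind = TRUE)
  tab <- data.frame(gene = rownames(x)[hits[, 1L]],
                    marker = markers$map$marker[hits[, 2L]],
                    r = r[hits], stringsAsFactors = FALSE)
  counts <- data.frame(marker = markers$map$marker,
                       n_pos_trans = 0L, n_neg_trans = 0L,
                       stringsAsFactors = FALSE)
  if (!is.null(gene_map) && nrow(tab)) {
    gchrom <- gene_map$chrom[match(tab$gene, gene_map$id)]
    mchrom <- markers$map$chrom[match(tab$marker, markers$map$marker)]
    trans <- gchrom != mchrom
    pos <- table(factor(tab$marker[trans & tab$r > 0], counts$marker))
    neg <- table(factor(tab$marker[trans & tab$r < 0], counts$marker))
    counts$n_pos_trans <- as.integer(pos)
    counts$n_neg_trans <- as.integer(neg)
  }
  list(table = tab, marker_counts = counts, r_cutoff = r_cutoff)
}

#' Pairing-permutation FDR for gene-marker associations
#'
#' Permutes the sample labels of the marker matrix as a block (gene-gene and
#' marker-marker correlation structures are both preserved; only the pairing
#' between the data types is destroyed), recounts retained associations, and
#' reports `FDR = mean permuted count / real count`, capped at 1.
#'
#' @param adj_expression,markers as in [gene_marker_correlations()].
#' @param r_cutoff retention cutoff.
#' @param n_perm number of pairing permutations.
#' @param seed permutation seed.
#' @return list with `fdr`, `real_count`, `perm_counts`.
#' @export
pairing_permutation_fdr <- function(adj_expression, markers, r_cutoff = 0.3,
                                    n_perm = 10L, seed = 1L) {
  x <- adj_matrix(adj_expression)
  shared <- intersect(colnames(x), colnames(markers$values))
  if (length(shared) < 10L) stop("fewer than 10 shared samples", call. = FALSE)
  xm <- t(x[, shared, drop = FALSE])
  mm <- t(markers$values[, shared, drop = FALSE])
  real <- sum(abs(stats::cor(xm, mm)) >= r_cutoff)
  perm_counts <- numeric(n_perm)
  with_substream(seed, "pairing_permutation", {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(nrow(mm))
      perm_counts[p] <- sum(abs(stats::cor(xm, mm[idx, , drop = FALSE])) >=
                              r_cutoff)
    }
  })
  fdr <- if (real > 0) min(mean(perm_counts) / real, 1) else 1
  list(fdr = fdr, real_count = real, perm_counts = perm_counts)
}

#' Detect trans-association hotspots
#'
#' Markers associated with more than `min_genes` genes at the correlation
#' cutoff (by default counting signed `r > r_cutoff` and excluding genes on
#' the marker's own chromosome) are hotspot candidates; candidates reduce to
#' the single top marker (largest gene count) per chromosome.
#'
#' @param correlations a [gene_marker_correlations()] result.
#' @param markers the [smooth_logr()] marker set.
#' @param gene_map gene map (`id`, `chrom`).
#' @param min_genes minimum associated-gene count (strictly exceeded).
#' @param r_cutoff correlation cutoff used for counting.
#' @param use_abs count `|r| > r_cutoff` instead of signed `r > r_cutoff`.
#' @param exclude_cis drop genes on the marker's own chromosome (default).
#' @return object of class `hotspot_set`: data frame (marker, chrom, pos,
#'   n_genes) with the per-hotspot gene lists in `regulons`.
#' @export
detect_hotspots <- function(correlations, markers, gene_map, min_genes = 500L,
                            r_cutoff = 0.3, use_abs = FALSE,
                            exclude_cis = TRUE) {
  tab <- correlations$table
  keep <- if (use_abs) abs(tab$r) > r_cutoff else tab$r > r_cutoff
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab)) {
    gchrom <- gene_map$chrom[match(tab$gene, gene_map$id)]
    mchrom <- markers$map$chrom[match(tab$marker, markers$map$marker)]
    if (exclude_cis) tab <- tab[gchrom != mchrom, , drop = FALSE]
  }
  counts <- table(tab$marker)
  cand <- names(counts)[counts > min_genes]
  hotspots <- data.frame(marker = character(), chrom = character(),
                         pos = numeric(), n_genes = integer(),
                         stringsAsFactors = FALSE)
  regulons <- list()
  if (length(cand)) {
    info <- markers$map[match(cand, markers$map$marker), ]
    info$n_genes <- as.integer(counts[cand])
    # single top marker per chromosome
    info <- info[order(info$chrom, -info$n_genes), ]
    info <- info[!duplicated(info$chrom), ]
    info <- info[order(-info$n_genes), ]
    hotspots <- data.frame(marker = info$marker, chrom = info$chrom,
                           pos = info$pos, n_genes = info$n_genes,
                           stringsAsFactors = FALSE)
    regulons <- lapply(info$marker, function(m) tab$gene[tab$marker == m])
    names(regulons) <- info$marker
  }
  structure(list(hotspots = hotspots, regulons = regulons,
                 min_genes = min_genes, r_cutoff = r_cutoff,
                 use_abs = use_abs, exclude_cis = exclude_cis),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("sCNV hotspots: %d marker(s) with > %d associated genes\n",
              nrow(x$hotspots), x$min_genes))
  if (nrow(x$hotspots)) print(x$hotspots, row.names = FALSE)
  invisible(x)
}

# adjusted R^2 and df-adjusted RMSE of a least-squares fit
fit_stats <- function(y, xmat) {
  fit <- stats::lm.fit(cbind(1, xmat), y)
  p <- ncol(xmat)
  n <- length(y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(adj_r2 = 1 - (sse / (n - p - 1)) / (sst / (n - 1)),
       rmse = sqrt(sse / (n - p - 1)), residuals = fit$residuals,
       rank = fit$rank)
}

cor_p <- function(r, n) {
  r <- clamp_r(r)
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
}

#' Forward stepwise variance decomposition of one gene onto sCNV markers
#'
#' Step 0 selects the single most correlated marker, provided its correlation
#' p-value meets `entry_p`; each later step considers the remaining marker
#' most correlated with the current residual on a chromosome not yet in the
#' model, and accepts it only if it also meets `entry_p` and strictly
#' decreases the residual-degrees-of-freedom RMSE. Selection stops otherwise.
#' All selected markers therefore sit on distinct chromosomes.
#'
#' @param y numeric gene trait across samples.
#' @param markers a [smooth_logr()] result (columns matching `y`'s samples).
#' @param entry_p marker entry p-value cutoff.
#' @return object of class `variance_model`: selected markers with partial
#'   sign and entry order, final adjusted R^2 (0 for the empty model), RMSE
#'   trace, and the entry p of the first marker.
#' @export
stepwise_variance <- function(y, markers, entry_p = 5.1e-6) {
  stopifnot(inherits(markers, "scnv_markers"))
  n <- length(y)
  if (n < 20L) stop("need at least 20 samples", call. = FALSE)
  mm <- t(markers$values)
  mchrom <- markers$map$chrom
  r0 <- as.numeric(stats::cor(y, mm))
  sel <- integer(0)
  rmse_trace <- sqrt(sum((y - mean(y))^2) / (n - 1))
  first_p <- NA_real_
  repeat {
    resid <- if (length(sel)) fit_stats(y, mm[, sel, drop = FALSE])$residuals
    else y - mean(y)
    avail <- which(!(mchrom %in% mchrom[sel]))
    if (!length(avail)) break
    rr <- as.numeric(stats::cor(resid, mm[, avail, drop = FALSE]))
    rr[is.na(rr)] <- 0
    best <- avail[which.max(abs(rr))]
    p <- cor_p(max(abs(rr)), n)
    if (length(sel) == 0L) first_p <- p
    if (p > entry_p) break
    new_sel <- c(sel, best)
    st <- fit_stats(y, mm[, new_sel, drop = FALSE])
    if (st$rank < length(new_sel) + 1L) {
      message("collinear candidate marker refused: ",
              markers$map$marker[best])
      break
    }
    if (st$rmse >= rmse_trace[length(rmse_trace)]) break
    sel <- new_sel
    rmse_trace <- c(rmse_trace, st$rmse)
  }
  if (length(sel)) {
    st <- fit_stats(y, mm[, sel, drop = FALSE])
    coefs <- stats::lm.fit(cbind(1, mm[, sel, drop = FALSE]), y)$coefficients[-1L]
    adj_r2 <- st$adj_r2
    signs <- sign(coefs)
  } else {
    adj_r2 <- 0
    signs <- numeric(0)
  }
  structure(list(
    selected = data.frame(marker = markers$map$marker[sel],
                          chrom = mchrom[sel], sign = as.numeric(signs),
                          step = seq_along(sel), stringsAsFactors = FALSE),
    adj_r2 = adj_r2, rmse_trace = rmse_trace, entry_p_first = first_p,
    entry_p = entry_p), class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf("Stepwise sCNV variance model: %d marker(s), adjusted R^2 = %.3f\n",
              nrow(x$selected), x$adj_r2))
  if (nrow(x$selected)) print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Stepwise variance decomposition for every gene
#'
#' Runs [stepwise_variance()] per gene, with a vectorized first-step
#' correlation screen so genes with no qualifying marker are skipped cheaply.
#'
#' @param adj_expression adjusted expression (gene x sample).
#' @param markers a [smooth_logr()] result sharing the samples.
#' @param entry_p entry p cutoff.
#' @return object of class `variance_models`: per-gene summary data frame
#'   (gene, n_markers, adj_r2, first_p) and the list of `variance_model`s
#'   for genes with a non-empty model.
#' @export
stepwise_variance_all <- function(adj_expression, markers, entry_p = 5.1e-6) {
  x <- adj_matrix(adj_expression)
  shared <- intersect(colnames(x), colnames(markers$values))
  x <- x[, shared, drop = FALSE]
  mk <- markers
  mk$values <- mk$values[, shared, drop = FALSE]
  n <- length(shared)
  r1 <- stats::cor(t(x), t(mk$values))
  best_r <- apply(abs(r1), 1L, max)
  pass <- cor_p(best_r, n) <= entry_p
  genes <- rownames(x)
  summary <- data.frame(gene = genes, n_markers = 0L, adj_r2 = 0,
                        first_p = cor_p(best_r, n), stringsAsFactors = FALSE)
  models <- list()
  for (j in which(pass)) {
    m <- stepwise_variance(x[j, ], mk, entry_p)
    summary$n_markers[j] <- nrow(m$selected)
    summary$adj_r2[j] <- m$adj_r2
    models[[genes[j]]] <- m
  }
  structure(list(summary = summary, models = models, entry_p = entry_p),
            class = "variance_models")
}

#' @export
print.variance_models <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Stepwise sCNV variance models for %d genes (entry p = %.3g)\n",
              nrow(s), x$entry_p))
  cat(sprintf("  %d genes with >= 1 marker; median adjusted R^2 among them %.3f\n",
              sum(s$n_markers > 0),
              stats::median(s$adj_r2[s$n_markers > 0])))
  invisible(x)
}

#' Summarize variance decomposition across genes
#'
#' Counts genes whose adjusted R^2 exceeds each cutoff, for the full
#' stepwise (trans+cis) models and for cis-only single-marker models, with a
#' permuted-control column when supplied, plus the distribution of genes by
#' number of markers in the model (1, 2, 3, >3).
#'
#' @param models a [stepwise_variance_all()] result.
#' @param cis_assignments a [nearest_cis_marker()] result.
#' @param adj_expression,markers data used to fit the cis-only models.
#' @param permuted_models optional [stepwise_variance_all()] on
#'   pairing-permuted data.
#' @param permuted_markers optional marker set with permuted sample labels,
#'   used for the permuted cis-only column.
#' @param cutoffs adjusted R^2 cutoffs.
#' @return list with `r2_counts` (data frame cutoff, trans_cis, cis, and
#'   permuted counterparts when supplied) and `marker_counts` (1, 2, 3, >3).
#' @export
variance_summary <- function(models, cis_assignments, adj_expression, markers,
                             permuted_models = NULL, permuted_markers = NULL,
                             cutoffs = c(0.1225, 0.2, 0.3, 0.4, 0.5, 0.6)) {
  s <- models$summary
  cis_r2 <- cis_only_r2(cis_assignments, adj_expression, markers,
                        models$entry_p)
  r2_counts <- data.frame(
    cutoff = cutoffs,
    trans_cis = vapply(cutoffs, function(ct) sum(s$adj_r2 > ct), 0L),
    cis = vapply(cutoffs, function(ct) sum(cis_r2 > ct, na.rm = TRUE), 0L))
  if (!is.null(permuted_models)) {
    sp <- permuted_models$summary
    r2_counts$pm_trans_cis <- vapply(cutoffs,
                                     function(ct) sum(sp$adj_r2 > ct), 0L)
  }
  if (!is.null(permuted_markers)) {
    pm_cis <- cis_only_r2(cis_assignments, adj_expression, permuted_markers,
                          models$entry_p)
    r2_counts$pm_cis <- vapply(cutoffs,
                               function(ct) sum(pm_cis > ct, na.rm = TRUE), 0L)
  }
  nm <- s$n_markers[s$n_markers > 0]
  marker_counts <- c(`1` = sum(nm == 1), `2` = sum(nm == 2),
                     `3` = sum(nm == 3), `>3` = sum(nm > 3))
  list(r2_counts = r2_counts, marker_counts = marker_counts)
}

#' Permute the sample pairing of a marker set
#'
#' Shuffles marker columns as a block (marker-marker correlations are
#' untouched; only the link to the expression samples is destroyed).
#'
#' @param markers a [smooth_logr()] result.
#' @param seed permutation seed.
#' @return a `scnv_markers` object with permuted sample assignment.
#' @export
permute_marker_samples <- function(markers, seed = 1L) {
  stopifnot(inherits(markers, "scnv_markers"))
  with_substream(seed, "marker_pairing", {
    idx <- sample.int(ncol(markers$values))
    out <- markers
    v <- markers$values[, idx, drop = FALSE]
    colnames(v) <- colnames(markers$values)
    out$values <- v
    out
  })
}

# adjusted R^2 of each gene on its nearest cis marker (NA without one;
# 0 when the cis correlation misses the entry threshold)
cis_only_r2 <- function(cis_assignments, adj_expression, markers, entry_p) {
  x <- adj_matrix(adj_expression)
  shared <- intersect(colnames(x), colnames(markers$values))
  x <- x[, shared, drop = FALSE]
  mv <- markers$values[, shared, drop = FALSE]
  n <- length(shared)
  out <- rep(NA_real_, nrow(x))
  idx <- match(cis_assignments$gene, rownames(x))
  for (k in seq_len(nrow(cis_assignments))) {
    g <- idx[k]
    m <- cis_assignments$marker[k]
    if (is.na(g) || is.na(m)) next
    r <- stats::cor(x[g, ], mv[m, ])
    if (is.na(r) || cor_p(r, n) > entry_p) {
      out[g] <- 0
    } else {
      out[g] <- fit_stats(x[g, ], cbind(mv[m, ]))$adj_r2
    }
  }
  out
}
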