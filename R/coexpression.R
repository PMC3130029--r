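#' Soft-threshold power adjacency
#'
#' Unsigned weighted-network adjacency `|r|^beta` with zero diagonal. The
#' unsigned convention keeps fractional exponents well defined for negative
#' correlations.
#'
#' @param correlation square correlation matrix with entries in `[-1, 1]`.
#' @param beta soft-threshold power (> 0).
#' @return adjacency matrix (symmetric, zero diagonal).
#' @export
power_adjacency <- function(correlation, beta) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  a <- abs(as.matrix(correlation))^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Connectivity `k` (adjacency row sums, or a supplied degree vector) is
#' binned into 10 equal-width bins; the frequency `p(k)` of occupied bins is
#' regressed as `log10 p(k)` on `log10 mean(k)` per bin. Returns the
#' R-squared of that fit (the index; 1 for a perfect scale-free network) and
#' the slope.
#'
#' @param adjacency adjacency matrix, or a numeric vector of connectivities.
#' @param n_bins number of equal-width connectivity bins.
#' @return list with `fit_index` (R-squared) and `slope`.
#' @export
scale_free_index <- function(adjacency, n_bins = 10L) {
  k <- if (is.matrix(adjacency)) rowSums(adjacency) else as.numeric(adjacency)
  k <- k[k > 0]
  if (length(unique(k)) < 2L) {
    stop("degenerate connectivity: all degrees equal", call. = FALSE)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  occupied <- which(freq > 0)
  if (length(occupied) < 5L) {
    stop("fewer than 5 occupied connectivity bins", call. = FALSE)
  }
  mean_k <- vapply(occupied, function(b) mean(k[bin == b]), 0)
  pk <- freq[occupied] / length(k)
  y <- log10(pk)
  if (stats::sd(y) < 1e-12) {
    # flat frequency profile: nothing to fit
    return(list(fit_index = 0, slope = 0))
  }
  fit <- stats::lm(y ~ log10(mean_k))
  list(fit_index = max(summary(fit)$r.squared, 0),
       slope = unname(stats::coef(fit)[2L]))
}

#' Select the soft-threshold power for scale-free topology
#'
#' Scans an ascending beta grid and picks the smallest beta whose
#' [scale_free_index()] reaches `fit_min`; when none does, the beta
#' maximizing the index is returned with a flag.
#'
#' @param correlation square correlation matrix.
#' @param betas ascending candidate powers.
#' @param fit_min required fit index.
#' @return list with `beta`, `fit_index`, `reached_fit_min`, and the scan
#'   table.
#' @export
select_beta <- function(correlation, betas = seq(1, 12, by = 0.5),
                        fit_min = 0.7) {
  if (is.unsorted(betas)) stop("beta grid must ascend", call. = FALSE)
  scan <- data.frame(beta = betas, fit_index = NA_real_, slope = NA_real_)
  for (i in seq_along(betas)) {
    sf <- tryCatch(scale_free_index(power_adjacency(correlation, betas[i])),
                   error = function(e) NULL)
    if (!is.null(sf)) {
      scan$fit_index[i] <- sf$fit_index
      scan$slope[i] <- sf$slope
    }
  }
  # scale-free means a *decreasing* p(k): require a negative slope
  ok <- which(!is.na(scan$fit_index) & scan$fit_index >= fit_min &
                scan$slope < 0)
  if (length(ok)) {
    i <- ok[1L]
    reached <- TRUE
  } else if (all(is.na(scan$fit_index))) {
    i <- 1L
    reached <- FALSE
  } else {
    i <- which.max(scan$fit_index)
    reached <- FALSE
  }
  list(beta = scan$beta[i], fit_index = scan$fit_index[i],
       reached_fit_min = reached, scan = scan)
}

#' Topological overlap similarity
#'
#' Unsigned TOM: `(sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' with unit diagonal.
#'
#' @param adjacency adjacency matrix.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

# color names in size order, grey reserved for unassigned
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "coral")

#' Detect coexpression modules from an adjacency matrix
#'
#' Computes topological-overlap dissimilarity, clusters genes by
#' average-linkage hierarchical clustering, applies a static tree cut at
#' dissimilarity `cut_height`, relabels clusters as colors in descending
#' size order, and sends clusters below `min_size` to `grey`.
#'
#' @param adjacency symmetric adjacency matrix with gene dimnames.
#' @param cut_height static cut height on the TOM dissimilarity scale
#'   (0 to 1); branches merging above it become separate modules.
#' @param min_size minimum module size.
#' @param beta,fit_index optional provenance recorded on the partition.
#' @param tissue optional tissue tag.
#' @return object of class `module_partition`: data frame `gene`, `module`,
#'   plus `beta`, `fit_index`, `n_modules` and the module size table.
#' @export
detect_modules <- function(adjacency, cut_height = 0.95, min_size = 30L,
                           beta = NA_real_, fit_index = NA_real_,
                           tissue = NULL) {
  a <- as.matrix(adjacency)
  genes <- rownames(a) %||% as.character(seq_len(nrow(a)))
  if (nrow(a) < min_size) {
    message("fewer genes than the minimum module size; all grey")
    part <- data.frame(gene = genes, module = "grey", stringsAsFactors = FALSE)
  } else {
    diss <- 1 - tom_similarity(a)
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_size]
    ord <- big[order(-sizes[big])]
    labels <- rep("grey", length(cl))
    for (i in seq_along(ord)) {
      lab <- if (i <= length(module_colors)) module_colors[i] else
        sprintf("module%02d", i)
      labels[cl == as.integer(ord[i])] <- lab
    }
    part <- data.frame(gene = genes, module = labels, stringsAsFactors = FALSE)
  }
  sizes <- sort(table(part$module[part$module != "grey"]), decreasing = TRUE)
  structure(list(partition = part, beta = beta, fit_index = fit_index,
                 n_modules = length(sizes), sizes = sizes, tissue = tissue),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Coexpression modules%s: %d modules over %d genes (beta = %s, fit index = %s)\n",
              if (is.null(x$tissue)) "" else paste0(" (", x$tissue, ")"),
              x$n_modules, nrow(x$partition),
              format(x$beta, digits = 3), format(x$fit_index, digits = 3)))
  if (x$n_modules) print(x$sizes)
  cat(sprintf("  grey (unassigned): %d genes\n",
              sum(x$partition$module == "grey")))
  invisible(x)
}

#' Build a weighted coexpression network and its module partition
#'
#' Pearson correlation across samples, soft-threshold selection by
#' [select_beta()] (unless `beta` is fixed), power adjacency, and
#' [detect_modules()].
#'
#' @param expression gene x sample matrix (or adjusted expression).
#' @param beta fixed soft threshold; NULL to select from `betas`.
#' @param betas,fit_min passed to [select_beta()].
#' @param cut_height,min_size passed to [detect_modules()].
#' @param tissue optional tag.
#' @return a `module_partition`.
#' @export
coexpression_network <- function(expression, beta = NULL,
                                 betas = seq(1, 12, by = 0.5), fit_min = 0.7,
                                 cut_height = 0.95, min_size = 30L,
                                 tissue = NULL) {
  x <- adj_matrix(expression)
  cr <- stats::cor(t(x))
  if (is.null(beta)) {
    sel <- select_beta(cr, betas, fit_min)
    beta <- sel$beta
    fit_index <- sel$fit_index
  } else {
    fit_index <- tryCatch(scale_free_index(power_adjacency(cr, beta))$fit_index,
                          error = function(e) NA_real_)
  }
  detect_modules(power_adjacency(cr, beta), cut_height, min_size,
                 beta = beta, fit_index = fit_index, tissue = tissue)
}

#' Map module overlaps across tissues
#'
#' All AN-module x TU-module Fisher exact enrichments over the shared gene
#' universe (grey included); records below `p_report` are flagged for
#' reporting.
#'
#' @param partition_an,partition_tu `module_partition`s on the same genes.
#' @param p_report reporting threshold.
#' @return data frame set1, set2, n1, n2, overlap, fold, p, significant.
#' @export
module_overlap_map <- function(partition_an, partition_tu, p_report = 1e-3) {
  pa <- partition_an$partition
  pt <- partition_tu$partition
  universe <- intersect(pa$gene, pt$gene)
  if (!length(universe)) stop("no shared genes", call. = FALSE)
  rows <- list()
  for (ma in unique(pa$module)) {
    ga <- intersect(pa$gene[pa$module == ma], universe)
    for (mt in unique(pt$module)) {
      gt <- intersect(pt$gene[pt$module == mt], universe)
      e <- fisher_enrichment(ga, gt, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        set1 = paste0("AN-", ma), set2 = paste0("TU-", mt),
        n1 = length(ga), n2 = length(gt), overlap = e$overlap,
        fold = e$fold, p = e$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < p_report
  out[order(out$p), ]
}
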