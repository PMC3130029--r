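#' Fisher exact over-representation of one gene set in another
#'
#' One-sided hypergeometric upper-tail p for the overlap of two sets inside
#' a common universe, with fold enrichment `overlap / expected` where
#' `expected = |A| * |B| / universe`.
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe character vector (or universe size, with `set_a`/`set_b`
#'   given as counts and `overlap` supplied).
#' @param overlap overlap count, only for counts mode.
#' @param n_tests optional Bonferroni multiplier for the adjusted p.
#' @return object of class `enrichment_record` (named list: sizes, overlap,
#'   expected, fold, p, p_adjusted).
#' @export
fisher_enrichment <- function(set_a, set_b, universe, overlap = NULL,
                              n_tests = 1L) {
  if (is.numeric(set_a) && length(set_a) == 1L) {
    n_a <- set_a
    n_b <- set_b
    n_u <- if (is.numeric(universe)) universe else length(universe)
    k <- overlap
    if (is.null(k)) stop("counts mode requires 'overlap'", call. = FALSE)
  } else {
    set_a <- unique(set_a)
    set_b <- unique(set_b)
    bad <- setdiff(c(set_a, set_b), universe)
    if (length(bad)) {
      stop("elements outside universe: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    n_a <- length(set_a)
    n_b <- length(set_b)
    n_u <- length(unique(universe))
    k <- length(intersect(set_a, set_b))
  }
  if (k > min(n_a, n_b)) stop("overlap exceeds a set size", call. = FALSE)
  expected <- n_a * n_b / n_u
  p <- stats::phyper(k - 1, n_b, n_u - n_b, n_a, lower.tail = FALSE)
  structure(list(n_a = n_a, n_b = n_b, universe = n_u, overlap = k,
                 expected = expected,
                 fold = if (expected > 0) k / expected else NA_real_,
                 p = p, p_adjusted = bonferroni_adjust(p, n_tests)),
            class = "enrichment_record")
}

#' @export
print.enrichment_record <- function(x, ...) {
  cat(sprintf("Enrichment: overlap %d of %d x %d in universe %d\n",
              x$overlap, x$n_a, x$n_b, x$universe))
  cat(sprintf("  expected %.2f, fold %.3g, p = %.3g (adjusted %.3g)\n",
              x$expected, x$fold, x$p, x$p_adjusted))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies p-values by the number of tests (capped at 1), or, when `p` is
#' omitted, returns the family-wise threshold `alpha / n_tests`.
#'
#' @param p p-value(s), or NULL for threshold mode.
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate for threshold mode.
#' @return adjusted p-value(s) or the threshold.
#' @export
bonferroni_adjust <- function(p = NULL, n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  if (is.null(p)) alpha / n_tests else pmin(1, p * n_tests)
}

#' Marker-adjusted enrichment of a gene set across marker strata
#'
#' For each sCNV marker, `expected = |test_set| * |assoc(marker)| / universe`
#' and `observed = |test_set intersect assoc(marker)|`; markers are pooled by
#' stratum (e.g. survival-predictive versus not) into
#' `ratio = sum(observed) / sum(expected)`, correcting for the non-uniform
#' distribution of gene-marker associations across the genome. Significance
#' per stratum is an exact two-sided binomial test of the pooled observed
#' count against the pooled association count at success probability
#' `|test_set| / universe`.
#'
#' @param test_set character vector of genes.
#' @param assoc_genes named list: marker -> associated gene vector.
#' @param universe character vector of all genes (or its size).
#' @param strata named vector mapping each marker to a stratum label.
#' @return data frame per stratum: n_markers, observed, expected, ratio,
#'   p (NA with a flag where the pooled expectation is 0).
#' @export
marker_adjusted_enrichment <- function(test_set, assoc_genes, universe,
                                       strata) {
  n_u <- if (is.numeric(universe)) universe else length(unique(universe))
  test_set <- unique(test_set)
  prob <- length(test_set) / n_u
  markers <- names(assoc_genes)
  if (is.null(markers) || !all(markers %in% names(strata))) {
    stop("every marker needs a stratum", call. = FALSE)
  }
  obs <- vapply(assoc_genes,
                function(g) length(intersect(g, test_set)), 0L)
  tot <- vapply(assoc_genes, length, 0L)
  exp_ <- length(test_set) * tot / n_u
  labs <- strata[markers]
  out <- lapply(unique(labs), function(st) {
    idx <- which(labs == st)
    so <- sum(obs[idx])
    se <- sum(exp_[idx])
    stot <- sum(tot[idx])
    p <- if (stot > 0 && prob > 0 && prob < 1) {
      stats::binom.test(so, stot, p = prob)$p.value
    } else NA_real_
    # an empty test set has ratio 0 by convention; a stratum with no
    # associated genes at all has an undefined ratio
    ratio <- if (se > 0) so / se else if (length(test_set) == 0L) 0 else
      NA_real_
    data.frame(stratum = st, n_markers = length(idx), observed = so,
               expected = se, ratio = ratio,
               undefined = se == 0 && length(test_set) > 0L, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Term enrichment across modules with unique-term differentials
#'
#' Tests every module x term combination by [fisher_enrichment()], applies a
#' Bonferroni correction over the total number of tests, and, among records
#' with adjusted p < 0.05, computes for each term the top module's fold and
#' `diff = fold - second-best significant module's fold` (`diff = fold` when
#' no other module is significant for that term).
#'
#' @param modules named list: module -> gene vector (disjoint membership).
#' @param gene_sets named list: term -> gene vector (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all genes.
#' @param alpha significance level on the adjusted p.
#' @return data frame: module, term, overlap, expected, fold, p, p_adjusted,
#'   significant, diff (non-NA only on the top significant record per term).
#' @export
unique_term_enrichment <- function(modules, gene_sets, universe,
                                   alpha = 0.05) {
  universe <- unique(universe)
  gene_sets <- lapply(gene_sets, function(g) intersect(unique(g), universe))
  empty <- vapply(gene_sets, length, 0L) == 0L
  if (any(empty)) {
    message("skipping terms with no genes in universe: ",
            paste(names(gene_sets)[empty], collapse = ", "))
    gene_sets <- gene_sets[!empty]
  }
  n_tests <- length(modules) * length(gene_sets)
  rows <- list()
  for (m in names(modules)) {
    for (tm in names(gene_sets)) {
      e <- fisher_enrichment(intersect(modules[[m]], universe),
                             gene_sets[[tm]], universe, n_tests = n_tests)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, term = tm, overlap = e$overlap, expected = e$expected,
        fold = e$fold, p = e$p, p_adjusted = e$p_adjusted,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  out$diff <- NA_real_
  for (tm in unique(out$term[out$significant])) {
    idx <- which(out$term == tm & out$significant)
    folds <- out$fold[idx]
    top <- idx[which.max(folds)]
    out$diff[top] <- if (length(idx) > 1L) {
      max(folds) - max(folds[-which.max(folds)])
    } else {
      out$fold[top]
    }
  }
  out
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines `name <tab> description <tab> member...`; duplicate
#' members within a set are dropped with a warning, empty sets skipped with
#' a warning; CRLF and LF files parse identically.
#'
#' @param path GMT file path.
#' @return named list of gene vectors; descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(parts) < 3L || !length(members)) {
      warning("skipping empty gene set line: ",
              substr(ln, 1, 40), call. = FALSE)
      next
    }
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s' deduplicated", parts[1L]),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[parts[1L]]] <- members
    desc[parts[1L]] <- parts[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}
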