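#' Single-covariate Cox proportional-hazards screen
#'
#' Fits, per feature, a proportional-hazards model with that single
#' standardized feature as covariate (Breslow convention for tied event
#' times) and reports the Wald two-sided p-value. Constant features get
#' `p = 1` with a flag.
#'
#' @param features feature x sample numeric matrix.
#' @param survival data frame `sample`, `time`, `event` (0/1) covering every
#'   feature column.
#' @param tissue optional tissue tag stored on the result.
#' @return object of class `cox_screen_result`: data frame with per-feature
#'   `coef` (log hazard per SD), `p` and `constant` flag.
#' @export
cox_screen <- function(features, survival, tissue = NULL) {
  features <- adj_matrix(features)
  sv <- survival[match(colnames(features), survival$sample), , drop = FALSE]
  if (anyNA(sv$time)) {
    stop("survival missing for samples: ",
         paste(colnames(features)[is.na(sv$time)], collapse = ", "),
         call. = FALSE)
  }
  if (sum(sv$event) == 0) stop("no events: cannot fit", call. = FALSE)
  if (sum(sv$event) < 10) stop("need at least 10 events", call. = FALSE)
  y <- survival::Surv(sv$time, sv$event)
  ord <- order(sv$time)
  y_ord <- y[ord, ]
  ctrl <- survival::coxph.control()
  g <- nrow(features)
  out <- data.frame(feature = rownames(features) %||% seq_len(g),
                    coef = NA_real_, p = NA_real_, constant = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(g)) {
    v <- features[j, ]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      out$coef[j] <- 0
      out$p[j] <- 1
      out$constant[j] <- TRUE
      next
    }
    x <- matrix((v - mean(v)) / s, ncol = 1)[ord, , drop = FALSE]
    fit <- tryCatch(
      survival::coxph.fit(x, y_ord, strata = NULL, offset = NULL,
                          init = 0, control = ctrl, weights = NULL,
                          method = "breslow", rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients) ||
        !is.finite(fit$var[1L]) || fit$var[1L] <= 0) {
      out$coef[j] <- NA_real_
      out$p[j] <- 1
      next
    }
    z <- fit$coefficients / sqrt(fit$var[1L])
    out$coef[j] <- unname(fit$coefficients)
    out$p[j] <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(results = out, tissue = tissue,
                 n_events = sum(sv$event), n_samples = nrow(sv)),
            class = "cox_screen_result")
}

#' @export
print.cox_screen_result <- function(x, ...) {
  cat(sprintf("Cox survival screen%s: %d features, %d events / %d samples\n",
              if (is.null(x$tissue)) "" else paste0(" (", x$tissue, ")"),
              nrow(x$results), x$n_events, x$n_samples))
  cat(sprintf("  features with p < 0.05: %d\n", sum(x$results$p < 0.05)))
  invisible(x)
}

#' Permute survival records against samples
#'
#' Shuffles `(time, event)` jointly across samples, preserving the marginal
#' censoring pattern.
#'
#' @param survival survival data frame.
#' @param seed permutation seed.
#' @return permuted survival data frame.
#' @export
permute_survival <- function(survival, seed = 1L) {
  with_substream(seed, "survival_permutation", {
    idx <- sample.int(nrow(survival))
    out <- survival
    out$time <- survival$time[idx]
    out$event <- survival$event[idx]
    out
  })
}

#' Empirical FDR-controlling p threshold from permutations
#'
#' `FDR(t) = mean permuted count of p <= t / real count of p <= t`, evaluated
#' on the sorted grid of real p-values; the threshold is the largest grid
#' value with FDR at or below the target (0 with a flag when none
#' qualifies).
#'
#' @param real_p real screening p-values.
#' @param perm_p list (or matrix with one column per permutation) of permuted
#'   p-value sets.
#' @param target_fdr target FDR (default 0.1).
#' @return list with `threshold`, `no_discoveries` flag and the `fdr_curve`
#'   data frame (threshold, real_count, mean_perm_count, fdr).
#' @export
empirical_fdr_threshold <- function(real_p, perm_p, target_fdr = 0.1) {
  if (is.matrix(perm_p)) perm_p <- asplit(perm_p, 2L)
  if (!length(perm_p)) stop("need at least one permutation set", call. = FALSE)
  grid <- sort(unique(real_p))
  real_count <- vapply(grid, function(t) sum(real_p <= t), 0L)
  perm_sorted <- lapply(perm_p, sort)
  perm_count <- rowMeans(vapply(perm_sorted,
                                function(p) findInterval(grid, p),
                                numeric(length(grid))))
  fdr <- ifelse(real_count > 0, pmin(perm_count / real_count, 1), 1)
  ok <- which(fdr <= target_fdr)
  threshold <- if (length(ok)) grid[max(ok)] else 0
  list(threshold = threshold, no_discoveries = length(ok) == 0,
       fdr_curve = data.frame(threshold = grid, real_count = real_count,
                              mean_perm_count = perm_count, fdr = fdr))
}

#' Cox screen with permutation-derived FDR threshold
#'
#' Runs [cox_screen()] on the real survival and on `n_perm` permuted copies,
#' derives the p threshold controlling the empirical FDR at `target_fdr`,
#' and flags significant features.
#'
#' @inheritParams cox_screen
#' @param n_perm number of survival permutations.
#' @param target_fdr target FDR.
#' @param seed permutation seed.
#' @return the `cox_screen_result` augmented with `threshold`,
#'   `target_fdr`, `fdr_curve`, and a `significant` column.
#' @export
cox_screen_fdr <- function(features, survival, n_perm = 100L,
                           target_fdr = 0.1, seed = 1L, tissue = NULL) {
  real <- cox_screen(features, survival, tissue = tissue)
  perm_p <- vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    sv <- permute_survival(survival,
                           seed = (as.numeric(seed) %% 1000003) + 1009 * k)
    perm_p[[k]] <- cox_screen(features, sv)$results$p
  }
  thr <- empirical_fdr_threshold(real$results$p, perm_p, target_fdr)
  real$results$significant <- real$results$p <= thr$threshold &
    thr$threshold > 0
  real$threshold <- thr$threshold
  real$no_discoveries <- thr$no_discoveries
  real$target_fdr <- target_fdr
  real$fdr_curve <- thr$fdr_curve
  real
}

#' Cross-tissue overlap of predictive feature sets
#'
#' Counts the overlap between AN- and TU-predictive sets, the percentage of
#' each set not predictive in the other tissue, and the fold enrichment of
#' the overlap against the chance expectation `|AN| * |TU| / universe`.
#'
#' @param an,tu character vectors of predictive features, or single counts
#'   (in which case `overlap` must be given).
#' @param universe universe size (count) or character vector.
#' @param overlap overlap count when `an`/`tu` are counts.
#' @return list with counts, exclusivity percentages and `fold`.
#' @export
cross_tissue_overlap <- function(an, tu, universe, overlap = NULL) {
  if (is.numeric(an) && length(an) == 1L) {
    n_an <- an
    n_tu <- tu
    n_ov <- overlap
    if (is.null(n_ov)) stop("counts mode requires 'overlap'", call. = FALSE)
    n_univ <- if (is.numeric(universe)) universe else length(universe)
  } else {
    n_an <- length(an)
    n_tu <- length(tu)
    n_ov <- length(intersect(an, tu))
    n_univ <- if (is.numeric(universe)) universe else length(universe)
  }
  if (n_univ < max(n_an, n_tu)) {
    stop("universe smaller than a predictive set", call. = FALSE)
  }
  expected <- n_an * n_tu / n_univ
  list(n_an = n_an, n_tu = n_tu, overlap = n_ov,
       an_only = n_an - n_ov, tu_only = n_tu - n_ov,
       pct_an_not_tu = 100 * (n_an - n_ov) / n_an,
       pct_tu_not_an = 100 * (n_tu - n_ov) / n_tu,
       expected = expected,
       fold = if (expected > 0) n_ov / expected else NA_real_)
}
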