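#' Robust covariate adjustment of expression by age and sex
#'
#' Fits, per gene, a robust linear model of expression on standardized age
#' and a 0/1 sex indicator using M-estimation with Tukey's bisquare weights
#' (tuning constant c = 4.685, 95\% Gaussian efficiency) and returns the
#' residuals as the adjusted gene trait. Genes whose robust fit does not
#' converge within `max_iter` iterations are flagged and fall back to
#' ordinary least-squares residuals.
#'
#' @param expression gene x sample numeric matrix (no missing values).
#' @param covariates data frame with columns `sample`, `age`, `sex`
#'   (0/1 or two-level factor); rows must cover every expression column.
#' @param max_iter maximum IRLS iterations.
#' @param c bisquare tuning constant; the default 4.685 gives 95\% Gaussian
#'   efficiency, and very large values recover ordinary least squares.
#' @return object of class `adjusted_expression`: list with `residuals`
#'   (same shape and dimnames as the input) and `fits` (per gene: intercept,
#'   age slope on the original age scale, sex effect, converged flag).
#' @export
robust_covariate_adjust <- function(expression, covariates, max_iter = 50L,
                                    c = 4.685) {
  if (ncol(expression) < 10L) stop("need at least 10 samples", call. = FALSE)
  if (anyNA(expression)) stop("missing expression values are not supported",
                              call. = FALSE)
  cov <- covariates[match(colnames(expression), covariates$sample), ,
                    drop = FALSE]
  if (anyNA(cov$age) || anyNA(cov$sex)) {
    stop("covariates incomplete for samples: ",
         paste(colnames(expression)[is.na(cov$age) | is.na(cov$sex)],
               collapse = ", "), call. = FALSE)
  }
  sex <- if (is.numeric(cov$sex)) cov$sex else
    as.integer(factor(cov$sex)) - 1L
  age_sd <- stats::sd(cov$age)
  keep_age <- isTRUE(age_sd > 0)
  if (!keep_age) warning("constant age column dropped")
  keep_sex <- stats::sd(sex) > 0
  if (!keep_sex) warning("constant sex column dropped")
  x <- cbind(intercept = rep(1, ncol(expression)),
             if (keep_age) (cov$age - mean(cov$age)) / age_sd,
             if (keep_sex) sex)
  colnames(x) <- c("intercept", if (keep_age) "age_std", if (keep_sex) "sex")

  g <- nrow(expression)
  res <- expression
  fits <- data.frame(gene = rownames(expression) %||% seq_len(g),
                     intercept = NA_real_, age_slope = NA_real_,
                     sex_effect = NA_real_, converged = NA,
                     stringsAsFactors = FALSE)
  for (j in seq_len(g)) {
    y <- expression[j, ]
    fit <- tryCatch(
      MASS::rlm(x, y, psi = MASS::psi.bisquare, c = c,
                maxit = max_iter, method = "M"),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      ls <- stats::lm.fit(x, y)
      res[j, ] <- ls$residuals
      cf <- ls$coefficients
      fits$converged[j] <- FALSE
    } else {
      res[j, ] <- stats::residuals(fit)
      cf <- stats::coef(fit)
      fits$converged[j] <- TRUE
    }
    fits$intercept[j] <- cf["intercept"]
    fits$age_slope[j] <- if (keep_age) cf["age_std"] / age_sd else 0
    fits$sex_effect[j] <- if (keep_sex) cf["sex"] else 0
  }
  structure(list(residuals = res, fits = fits), class = "adjusted_expression")
}

#' @export
print.adjusted_expression <- function(x, ...) {
  cat(sprintf("Covariate-adjusted expression: %d genes x %d samples (%.1f%% converged)\n",
              nrow(x$residuals), ncol(x$residuals),
              100 * mean(x$fits$converged)))
  invisible(x)
}

# accept either the container or a bare matrix downstream
adj_matrix <- function(x) {
  if (inherits(x, "adjusted_expression")) x$residuals else as.matrix(x)
}

#' Paired differential expression between tissues
#'
#' Two-sided paired t-test per gene on matched AN/TU differences.
#'
#' @param expression_an,expression_tu gene x sample matrices with shared gene
#'   rows.
#' @param pairing optional named character vector mapping AN sample names to
#'   TU sample names; by default columns are matched by name.
#' @return data frame with per-gene `t`, `p` and a `zero_variance` flag
#'   (`p = 1` where all differences are identical).
#' @export
paired_differential_expression <- function(expression_an, expression_tu,
                                           pairing = NULL) {
  an <- adj_matrix(expression_an)
  tu <- adj_matrix(expression_tu)
  if (!identical(rownames(an), rownames(tu))) {
    stop("gene rows differ between tissues", call. = FALSE)
  }
  if (is.null(pairing)) {
    missing_tu <- setdiff(colnames(an), colnames(tu))
    missing_an <- setdiff(colnames(tu), colnames(an))
    if (length(missing_tu) || length(missing_an)) {
      stop("unmatched samples: ",
           paste(c(missing_tu, missing_an), collapse = ", "), call. = FALSE)
    }
    tu <- tu[, colnames(an), drop = FALSE]
  } else {
    bad <- setdiff(colnames(an), names(pairing))
    bad2 <- setdiff(pairing[colnames(an)], colnames(tu))
    if (length(bad) || length(bad2)) {
      stop("unmatched samples: ", paste(c(bad, bad2), collapse = ", "),
           call. = FALSE)
    }
    tu <- tu[, pairing[colnames(an)], drop = FALSE]
  }
  n <- ncol(an)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- tu - an
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  p <- ifelse(s > 0, 2 * stats::pt(-abs(tstat), df = n - 1), 1)
  data.frame(gene = rownames(an), t = tstat, p = p, zero_variance = s == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Center features within sample groups
#'
#' Subtracts, per feature, the group mean within each group of samples
#' (e.g. to remove tissue-of-origin effects before pooled correlation).
#'
#' @param mat feature x sample matrix.
#' @param group_labels vector of group labels, one per column.
#' @return matrix of the same shape with zero group means per feature.
#' @export
group_mean_adjust <- function(mat, group_labels) {
  mat <- as.matrix(mat)
  if (length(group_labels) != ncol(mat)) {
    stop("every sample must be labeled", call. = FALSE)
  }
  for (gr in unique(group_labels)) {
    idx <- which(group_labels == gr)
    if (length(idx) == 1L) {
      warning(sprintf("group '%s' has a single sample; values become 0", gr))
    }
    mat[, idx] <- mat[, idx, drop = FALSE] -
      rowMeans(mat[, idx, drop = FALSE])
  }
  mat
}
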