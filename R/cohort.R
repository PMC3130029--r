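#' Configuration for the synthetic paired-cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' describe a desk-scale paired hepatocellular-carcinoma-like cohort: matched
#' adjacent-normal (AN) and tumor (TU) tissue from the same patients, whole-arm
#' scale somatic copy-number segments confined to TU, cis dosage effects on
#' local genes, trans hotspot regulons, latent coexpression modules that are
#' partially disrupted during tumorigenesis, TU-specific modules, small
#' age/sex covariate effects, and exponential proportional-hazards survival
#' linked to designated genes.
#'
#' @param n_pairs number of matched AN/TU sample pairs.
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes (each `chromosome_length` bp).
#' @param snps_per_chromosome SNPs placed per chromosome.
#' @param chromosome_length chromosome length in bp.
#' @param scnv_event_rate expected Poisson number of somatic segments per TU
#'   sample genome.
#' @param scnv_amplitude_sd standard deviation (logR units) of segment
#'   amplitudes.
#' @param logr_noise_sd baseline logR measurement noise (both tissues).
#' @param min_segment_snps minimum segment length in SNPs (default twice the
#'   standard 40-SNP smoothing window, mimicking whole-arm events).
#' @param cis_effect standardized slope of a cis-driven gene on its local
#'   smoothed dosage.
#' @param cis_window cis window half-width in bp.
#' @param n_hotspots number of trans hotspot loci (distinct chromosomes).
#' @param hotspot_regulon_size genes per hotspot regulon.
#' @param hotspot_freq fraction of TU samples carrying each hotspot segment.
#' @param trans_effect standardized slope of regulon genes on hotspot dosage.
#' @param n_an_modules,n_tu_modules latent coexpression factor counts for AN
#'   and TU-only modules.
#' @param module_size genes per latent module.
#' @param disruption_fraction fraction of each AN module's loadings zeroed in
#'   TU.
#' @param survival_genes_an,survival_genes_tu counts of hazard-linked genes
#'   whose AN (resp. TU) expression enters the log hazard.
#' @param hazard_coef log-hazard increment per standard-deviation unit of
#'   summed survival-gene expression.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param censor_rate target fraction of censored samples.
#' @param age_effect_sd,sex_effect_sd standard deviations of per-gene age and
#'   sex coefficients (expression units per SD of age / per sex class).
#' @param tumor_shift_sd standard deviation of per-gene TU mean shifts
#'   (drives paired differential expression).
#' @param noise_sd expression residual standard deviation.
#' @param seed master seed; every downstream draw is a pure function of it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_pairs = 200L, n_genes = 2000L, n_chromosomes = 8L,
                       snps_per_chromosome = 300L, chromosome_length = 1e8,
                       scnv_event_rate = 5, scnv_amplitude_sd = 0.5,
                       logr_noise_sd = 0.1, min_segment_snps = 80L,
                       cis_effect = 0.5, cis_window = 5e6,
                       n_hotspots = 2L, hotspot_regulon_size = 100L,
                       hotspot_freq = 0.5, trans_effect = 0.5,
                       n_an_modules = 5L, n_tu_modules = 3L, module_size = 50L,
                       disruption_fraction = 0.5,
                       survival_genes_an = 2L, survival_genes_tu = 2L,
                       hazard_coef = 0.7, baseline_hazard = log(2) / 36,
                       censor_rate = 0.3,
                       age_effect_sd = 0.1, sex_effect_sd = 0.1,
                       tumor_shift_sd = 0.3, noise_sd = 0.5, seed = 1L) {
  stop_if_not_count(n_pairs, "n_pairs")
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_chromosomes, "n_chromosomes")
  stop_if_not_count(snps_per_chromosome, "snps_per_chromosome")
  stop_if_not_count(min_segment_snps, "min_segment_snps", min = 2L)
  stop_if_not_count(n_hotspots, "n_hotspots", min = 0L)
  stop_if_not_count(n_an_modules, "n_an_modules", min = 0L)
  stop_if_not_count(n_tu_modules, "n_tu_modules", min = 0L)
  stop_if_not_count(module_size, "module_size", min = 2L)
  stop_if_not_count(survival_genes_an, "survival_genes_an", min = 0L)
  stop_if_not_count(survival_genes_tu, "survival_genes_tu", min = 0L)
  stop_if_not_fraction(disruption_fraction, "disruption_fraction")
  stop_if_not_fraction(censor_rate, "censor_rate")
  stop_if_not_fraction(hotspot_freq, "hotspot_freq")
  if (scnv_event_rate < 0) stop("'scnv_event_rate' must be >= 0", call. = FALSE)
  if (noise_sd <= 0 || logr_noise_sd <= 0) {
    stop("noise standard deviations must be > 0", call. = FALSE)
  }
  if (n_hotspots > 0) {
    stop_if_not_count(hotspot_regulon_size, "hotspot_regulon_size")
    if (hotspot_regulon_size >= n_genes) {
      stop("hotspot regulon larger than gene count", call. = FALSE)
    }
    if (n_hotspots > n_chromosomes) {
      stop("more hotspots than chromosomes", call. = FALSE)
    }
  }
  used <- n_an_modules * module_size + n_tu_modules * module_size +
    n_hotspots * hotspot_regulon_size
  if (used > n_genes) {
    stop("modules and regulons require more genes than 'n_genes' provides",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic paired-cohort configuration\n")
  cat(sprintf("  %d matched pairs, %d genes, %d chromosomes x %d SNPs\n",
              x$n_pairs, x$n_genes, x$n_chromosomes, x$snps_per_chromosome))
  cat(sprintf("  sCNV: rate %.2f, amplitude sd %.2f; cis effect %.2f; %d hotspot(s)\n",
              x$scnv_event_rate, x$scnv_amplitude_sd, x$cis_effect, x$n_hotspots))
  cat(sprintf("  modules: %d AN / %d TU (size %d), disruption %.2f\n",
              x$n_an_modules, x$n_tu_modules, x$module_size, x$disruption_fraction))
  cat(sprintf("  survival genes: %d AN / %d TU, hazard coef %.2f; seed %d\n",
              x$survival_genes_an, x$survival_genes_tu, x$hazard_coef, x$seed))
  invisible(x)
}

#' Place genes and SNPs on a synthetic genome
#'
#' Features are allocated equally across chromosomes (remainders go to the
#' first chromosomes) with uniform, deduplicated, strictly increasing
#' positions within each chromosome.
#'
#' @param config a [sim_config()].
#' @return list with `gene_map` and `snp_map` data frames
#'   (`id`, `chrom`, `pos`; positions 1-based).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "genome", {
    gene_map <- place_features(config$n_genes, config$n_chromosomes,
                               config$chromosome_length, "g")
    snp_map <- place_features(config$n_chromosomes * config$snps_per_chromosome,
                              config$n_chromosomes, config$chromosome_length, "s")
    list(gene_map = gene_map, snp_map = snp_map)
  })
}

place_features <- function(n, n_chrom, chrom_len, prefix) {
  per <- rep(n %/% n_chrom, n_chrom)
  extra <- n %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per)
  pos <- unlist(lapply(per, function(k) sort(sample.int(chrom_len, k))),
                use.names = FALSE)
  data.frame(id = sprintf("%s%0*d", prefix, nchar(n) + 1L, seq_len(n)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate somatic copy-number logR profiles
#'
#' TU samples carry `Poisson(scnv_event_rate)` contiguous segments per genome
#' with amplitudes `Normal(0, scnv_amplitude_sd)` added on top of baseline
#' `Normal(0, logr_noise_sd)` logR noise; hotspot loci (fixed central segments
#' on distinct chromosomes) recur across a `hotspot_freq` fraction of TU
#' samples. AN samples carry noise only, matching the near-absence of somatic
#' events in non-tumor tissue.
#'
#' @param config a [sim_config()].
#' @param snp_map SNP map from [simulate_genome()].
#' @return list with `logr_an`, `logr_tu` (SNP x sample matrices) and
#'   `segments` (truth table: sample, chrom, SNP and bp ranges, amplitude,
#'   type `random`/`hotspot`).
#' @export
simulate_scnv_profiles <- function(config, snp_map) {
  stopifnot(inherits(config, "sim_config"))
  n_snp <- nrow(snp_map)
  n <- config$n_pairs
  samples <- sprintf("P%03d", seq_len(n))
  with_substream(config$seed, "scnv", {
    logr_an <- matrix(stats::rnorm(n_snp * n, 0, config$logr_noise_sd),
                      n_snp, n, dimnames = list(snp_map$id, samples))
    logr_tu <- matrix(stats::rnorm(n_snp * n, 0, config$logr_noise_sd),
                      n_snp, n, dimnames = list(snp_map$id, samples))
    chroms <- unique(snp_map$chrom)
    chrom_rows <- lapply(chroms, function(ch) which(snp_map$chrom == ch))
    names(chrom_rows) <- chroms
    minlen <- config$min_segment_snps
    seg <- list()
    # random whole-arm scale segments, TU only
    for (s in seq_len(n)) {
      n_ev <- stats::rpois(1L, config$scnv_event_rate)
      if (n_ev == 0) next
      for (e in seq_len(n_ev)) {
        ch <- sample(chroms, 1L)
        rows <- chrom_rows[[ch]]
        m <- length(rows)
        if (m < minlen) next
        start <- sample.int(m - minlen + 1L, 1L)
        end <- if (start + minlen - 1L >= m) m else
          sample(seq(start + minlen - 1L, m), 1L)
        amp <- stats::rnorm(1L, 0, config$scnv_amplitude_sd)
        idx <- rows[start:end]
        logr_tu[idx, s] <- logr_tu[idx, s] + amp
        seg[[length(seg) + 1L]] <- data.frame(
          sample = samples[s], chrom = ch, start_snp = start, end_snp = end,
          start_pos = snp_map$pos[idx[1L]], end_pos = snp_map$pos[idx[length(idx)]],
          amplitude = amp, type = "random", hotspot = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    # recurrent hotspot segments at fixed loci
    hotspot_loci <- NULL
    if (config$n_hotspots > 0) {
      hot_chroms <- sample(chroms, config$n_hotspots)
      loci <- list()
      for (h in seq_len(config$n_hotspots)) {
        rows <- chrom_rows[[hot_chroms[h]]]
        m <- length(rows)
        len <- min(minlen, m)
        start <- max(1L, (m - len) %/% 2L)
        end <- start + len - 1L
        idx <- rows[start:end]
        loci[[h]] <- data.frame(hotspot = h, chrom = hot_chroms[h],
                                start_snp = start, end_snp = end,
                                stringsAsFactors = FALSE)
        carrier <- stats::runif(n) < config$hotspot_freq
        amps <- stats::rnorm(n, 0, config$scnv_amplitude_sd)
        for (s in which(carrier)) {
          logr_tu[idx, s] <- logr_tu[idx, s] + amps[s]
          seg[[length(seg) + 1L]] <- data.frame(
            sample = samples[s], chrom = hot_chroms[h], start_snp = start,
            end_snp = end, start_pos = snp_map$pos[idx[1L]],
            end_pos = snp_map$pos[idx[length(idx)]], amplitude = amps[s],
            type = "hotspot", hotspot = h, stringsAsFactors = FALSE)
        }
      }
      hotspot_loci <- do.call(rbind, loci)
    }
    segments <- if (length(seg)) do.call(rbind, seg) else
      data.frame(sample = character(), chrom = character(),
                 start_snp = integer(), end_snp = integer(),
                 start_pos = integer(), end_pos = integer(),
                 amplitude = numeric(), type = character(),
                 hotspot = integer(), stringsAsFactors = FALSE)
    attr(segments, "hotspot_loci") <- hotspot_loci
    list(logr_an = logr_an, logr_tu = logr_tu, segments = segments)
  })
}

#' Simulate AN and TU expression with implanted network structure
#'
#' AN expression follows a latent factor model (one factor per AN module,
#' unit loadings on member genes) plus linear age and additive sex effects
#' and Gaussian noise. TU expression reuses the AN factor structure with a
#' `disruption_fraction` of loadings zeroed per module, adds TU-only module
#' factors, cis dosage effects (`cis_effect` times the standardized local
#' mean TU logR for genes whose cis window shows real dosage variance),
#' hotspot regulon effects (`trans_effect` times standardized hotspot dosage),
#' a per-gene tumor mean shift, and noise.
#'
#' @param config a [sim_config()].
#' @param gene_map,snp_map maps from [simulate_genome()].
#' @param logr_tu TU logR matrix from [simulate_scnv_profiles()].
#' @param segments segment truth table from [simulate_scnv_profiles()].
#' @return list with `expression_an`, `expression_tu`, `covariates`
#'   (sample, age, sex) and a `truth` list (modules, disrupted/created pairs,
#'   cis-driven genes, hotspot regulons).
#' @export
simulate_expression <- function(config, gene_map, snp_map, logr_tu, segments) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_pairs
  g <- config$n_genes
  samples <- colnames(logr_tu)
  covariates <- with_substream(config$seed, "covariates", {
    data.frame(sample = samples,
               age = round(stats::rnorm(n, 55, 10)),
               sex = stats::rbinom(n, 1L, 0.65),
               stringsAsFactors = FALSE)
  })
  with_substream(config$seed, "expression", {
    free <- seq_len(g)
    take <- function(k) {
      sel <- sample(free, k)
      free <<- setdiff(free, sel)
      sel
    }
    an_modules <- lapply(seq_len(config$n_an_modules),
                         function(i) take(config$module_size))
    tu_modules <- lapply(seq_len(config$n_tu_modules),
                         function(i) take(config$module_size))
    hotspot_loci <- attr(segments, "hotspot_loci")
    regulons <- list()
    for (h in seq_len(NROW(hotspot_loci))) {
      # regulon genes live on other chromosomes (pure trans regulation)
      cand <- intersect(free, which(gene_map$chrom != hotspot_loci$chrom[h]))
      sel <- sample(cand, min(config$hotspot_regulon_size, length(cand)))
      free <- setdiff(free, sel)
      regulons[[h]] <- sel
    }

    baseline <- stats::rnorm(g, 8, 0.5)
    beta_age <- stats::rnorm(g, 0, config$age_effect_sd)
    beta_sex <- stats::rnorm(g, 0, config$sex_effect_sd)
    age_std <- as.numeric(scale(covariates$age))
    sex <- covariates$sex
    covar <- outer(beta_age, age_std) + outer(beta_sex, sex)

    expr_an <- matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n,
                      dimnames = list(gene_map$id, samples))
    expr_tu <- matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n,
                      dimnames = list(gene_map$id, samples))
    expr_an <- expr_an + baseline + covar
    tumor_shift <- stats::rnorm(g, 0, config$tumor_shift_sd)
    expr_tu <- expr_tu + baseline + tumor_shift + covar

    disrupted <- integer(0)
    for (m in seq_along(an_modules)) {
      genes <- an_modules[[m]]
      f_an <- stats::rnorm(n)
      f_tu <- stats::rnorm(n)
      expr_an[genes, ] <- expr_an[genes, ] + rep(f_an, each = length(genes))
      n_zero <- floor(config$disruption_fraction * length(genes))
      zeroed <- if (n_zero > 0) sample(genes, n_zero) else integer(0)
      kept <- setdiff(genes, zeroed)
      if (length(kept)) {
        expr_tu[kept, ] <- expr_tu[kept, ] + rep(f_tu, each = length(kept))
      }
      disrupted <- c(disrupted, zeroed)
    }
    for (m in seq_along(tu_modules)) {
      genes <- tu_modules[[m]]
      f_tu <- stats::rnorm(n)
      expr_tu[genes, ] <- expr_tu[genes, ] + rep(f_tu, each = length(genes))
    }

    # cis dosage: local mean TU logR within the cis window of each gene;
    # genes over loci with real segment-driven variance get the effect
    dosage <- local_dosage(gene_map, snp_map, logr_tu, config$cis_window)
    dsd <- apply(dosage, 1L, stats::sd)
    cis_idx <- which(dsd > 0.1 & config$cis_effect != 0)
    if (length(cis_idx)) {
      dz <- dosage[cis_idx, , drop = FALSE]
      dz <- (dz - rowMeans(dz)) / dsd[cis_idx]
      expr_tu[cis_idx, ] <- expr_tu[cis_idx, ] + config$cis_effect * dz
    }

    for (h in seq_along(regulons)) {
      genes <- regulons[[h]]
      if (!length(genes)) next
      rows <- which(snp_map$chrom == hotspot_loci$chrom[h])
      idx <- rows[hotspot_loci$start_snp[h]:hotspot_loci$end_snp[h]]
      dose <- colMeans(logr_tu[idx, , drop = FALSE])
      dz <- as.numeric(scale(dose))
      expr_tu[genes, ] <- expr_tu[genes, ] +
        config$trans_effect * rep(dz, each = length(genes))
    }

    ids <- gene_map$id
    truth <- list(
      an_modules = lapply(an_modules, function(i) ids[i]),
      tu_modules = lapply(tu_modules, function(i) ids[i]),
      disrupted_genes = ids[disrupted],
      disrupted_pairs = module_pairs(an_modules, disrupted, ids),
      created_pairs = all_module_pairs(tu_modules, ids),
      cis_driven_genes = ids[cis_idx],
      hotspots = hotspot_loci,
      hotspot_regulons = lapply(regulons, function(i) ids[i]))
    list(expression_an = expr_an, expression_tu = expr_tu,
         covariates = covariates, truth = truth)
  })
}

# pairs within AN modules touching at least one disrupted gene: correlated in
# AN, decorrelated in TU
module_pairs <- function(modules, disrupted, ids) {
  out <- list()
  for (genes in modules) {
    zeroed <- intersect(genes, disrupted)
    if (!length(zeroed)) next
    kept <- setdiff(genes, zeroed)
    pr <- rbind(
      if (length(zeroed) > 1) t(utils::combn(sort(zeroed), 2L)) else NULL,
      if (length(kept) && length(zeroed))
        as.matrix(expand.grid(gene_i = zeroed, gene_j = kept)) else NULL)
    if (!is.null(pr)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_i = ids[pmin(as.integer(pr[, 1L]), as.integer(pr[, 2L]))],
        gene_j = ids[pmax(as.integer(pr[, 1L]), as.integer(pr[, 2L]))],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_i = character(), gene_j = character(),
               stringsAsFactors = FALSE)
}

all_module_pairs <- function(modules, ids) {
  out <- lapply(modules, function(genes) {
    if (length(genes) < 2) return(NULL)
    pr <- t(utils::combn(sort(genes), 2L))
    data.frame(gene_i = ids[pr[, 1L]], gene_j = ids[pr[, 2L]],
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_i = character(), gene_j = character(),
               stringsAsFactors = FALSE)
}

# mean logR over SNPs within +/- window of each gene (gene x sample)
local_dosage <- function(gene_map, snp_map, logr, window) {
  out <- matrix(NA_real_, nrow(gene_map), ncol(logr),
                dimnames = list(gene_map$id, colnames(logr)))
  for (ch in unique(gene_map$chrom)) {
    rows <- which(snp_map$chrom == ch)
    if (!length(rows)) next
    pos <- snp_map$pos[rows]
    gi <- which(gene_map$chrom == ch)
    lo <- findInterval(gene_map$pos[gi] - window, pos) + 1L
    hi <- findInterval(gene_map$pos[gi] + window, pos)
    for (k in seq_along(gi)) {
      if (hi[k] < lo[k]) next
      idx <- rows[lo[k]:hi[k]]
      out[gi[k], ] <- colMeans(logr[idx, , drop = FALSE])
    }
  }
  out[is.na(out[, 1L]), ] <- 0
  out
}

#' Simulate censored survival linked to designated genes
#'
#' Event times are exponential with log hazard
#' `hazard_coef * (sum of standardized AN-survival-gene AN expression +
#' sum of standardized TU-survival-gene TU expression)` over the baseline
#' hazard; independent exponential censoring is tuned so that roughly
#' `censor_rate` of samples are censored. `censor_rate = 1` yields an
#' all-censored cohort (every event indicator 0).
#'
#' @param config a [sim_config()].
#' @param expression_an,expression_tu gene x sample matrices.
#' @param truth truth list from [simulate_expression()]; survival-gene lists
#'   are appended to it.
#' @return list with `survival` (sample, time in months, event 0/1) and the
#'   augmented `truth`.
#' @export
simulate_survival <- function(config, expression_an, expression_tu, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- ncol(expression_an)
  samples <- colnames(expression_an)
  with_substream(config$seed, "survival", {
    ids <- rownames(expression_an)
    pool <- ids
    sg_an <- if (config$survival_genes_an > 0)
      sample(pool, config$survival_genes_an) else character(0)
    pool <- setdiff(pool, sg_an)
    sg_tu <- if (config$survival_genes_tu > 0)
      sample(pool, config$survival_genes_tu) else character(0)
    eta <- rep(0, n)
    if (length(sg_an)) {
      z <- scale(t(expression_an[sg_an, , drop = FALSE]))
      eta <- eta + rowSums(z)
    }
    if (length(sg_tu)) {
      z <- scale(t(expression_tu[sg_tu, , drop = FALSE]))
      eta <- eta + rowSums(z)
    }
    rate <- config$baseline_hazard * exp(config$hazard_coef * eta)
    t_event <- stats::rexp(n, rate)
    if (config$censor_rate >= 1) {
      time <- stats::rexp(n, config$baseline_hazard)
      event <- rep(0L, n)
    } else if (config$censor_rate <= 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      c_rate <- config$baseline_hazard *
        config$censor_rate / (1 - config$censor_rate)
      t_cens <- stats::rexp(n, c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    truth$survival_genes_an <- sg_an
    truth$survival_genes_tu <- sg_tu
    list(survival = data.frame(sample = samples, time = time, event = event,
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a complete synthetic paired cohort with ground truth
#'
#' Composes [simulate_genome()], [simulate_scnv_profiles()],
#' [simulate_expression()] and [simulate_survival()]. Identical
#' configurations (including seed) yield identical cohorts; each stage draws
#' from its own named substream so adding a stage never perturbs earlier ones.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given the cohort and truth tables are
#'   written there via [write_cohort()].
#' @return list with `cohort` (class `paired_cohort`) and `truth`.
#' @export
generate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  maps <- simulate_genome(config)
  scnv <- simulate_scnv_profiles(config, maps$snp_map)
  ex <- simulate_expression(config, maps$gene_map, maps$snp_map,
                            scnv$logr_tu, scnv$segments)
  sv <- simulate_survival(config, ex$expression_an, ex$expression_tu, ex$truth)
  truth <- sv$truth
  truth$scnv_segments <- scnv$segments
  cohort <- structure(list(
    expression_an = ex$expression_an, expression_tu = ex$expression_tu,
    logr_an = scnv$logr_an, logr_tu = scnv$logr_tu,
    gene_map = maps$gene_map, snp_map = maps$snp_map,
    covariates = ex$covariates, survival = sv$survival,
    config = config), class = "paired_cohort")
  if (!is.null(dir)) write_cohort(cohort, truth, dir)
  list(cohort = cohort, truth = truth)
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("Paired AN/TU cohort\n")
  cat(sprintf("  %d matched pairs; %d genes; %d SNPs on %d chromosomes\n",
              ncol(x$expression_an), nrow(x$expression_an), nrow(x$logr_an),
              length(unique(x$snp_map$chrom))))
  cat(sprintf("  survival: %d events / %d samples\n",
              sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}
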