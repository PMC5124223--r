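#' Exposure models for the synthetic cohort
#'
#' `exposure_zero_inflated()` describes a continuous biomarker exposure in
#' which most samples are exact zeros (non-smokers with no detectable
#' cotinine) and the positive part is lognormal with the given mean and
#' standard deviation. The defaults mirror a cohort in which 736 of 1062
#' mothers had no detectable cotinine and the 326 with detectable levels
#' averaged 191 (SD ~ 199, from the reported standard error of 11).
#'
#' `exposure_categorical3()` describes a three-category smoking report
#' (none / stopped during pregnancy / smoked throughout), encoded 0/1/2 by
#' [encode_categorical_exposure()]. Default probabilities follow the
#' replication cohort split 512/103/70.
#'
#' @param p_zero probability of a zero (undetectable) exposure.
#' @param mean_pos,sd_pos mean and SD of the positive (detected) part.
#' @param probs named probabilities for the levels none/stopped/throughout;
#'   normalized to sum to 1.
#' @return A list describing the model, for use in [sim_config()].
#' @export
exposure_zero_inflated <- function(p_zero = 736 / 1062, mean_pos = 191,
                                   sd_pos = 199) {
  stopifnot(p_zero >= 0, p_zero <= 1, mean_pos > 0, sd_pos > 0)
  list(type = "continuous_zero_inflated", p_zero = p_zero,
       mean_pos = mean_pos, sd_pos = sd_pos)
}

#' @rdname exposure_zero_inflated
#' @export
exposure_categorical3 <- function(probs = c(none = 512, stopped = 103,
                                            throughout = 70) / 685) {
  if (is.null(names(probs))) names(probs) <- c("none", "stopped", "throughout")
  stopifnot(length(probs) == 3L, all(probs >= 0), sum(probs) > 0)
  if (!all(names(probs) == c("none", "stopped", "throughout"))) {
    stop("probs must be named none/stopped/throughout, in that order")
  }
  list(type = "categorical3", probs = probs / sum(probs))
}

#' Configuration for the synthetic-cohort generator
#'
#' Collects and validates all parameters of [generate_cohort()]. Within-gene
#' CpG correlation is induced by a one-factor Gaussian copula on the
#' logit-beta scale (see the methods vignette); `delta` values in
#' `effect_genes` are per-unit-of-exposure shifts of the affected gene's CpG
#' beta values, applied after the copula and clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes; gene ids are `gene_ids(n_genes)`.
#' @param cpgs_per_gene integer range `c(min, max)`; each gene's CpG count is
#'   drawn uniformly from it.
#' @param within_gene_correlation latent pairwise correlation `rho` in `[0, 1)`
#'   between CpGs of the same gene.
#' @param exposure_model [exposure_zero_inflated()] or
#'   [exposure_categorical3()].
#' @param n_candidate_covariates number of candidate covariates, drawn
#'   independently of the exposure (a mix of continuous and categorical,
#'   named after typical questionnaire variables).
#' @param effect_genes named numeric vector: names are gene ids, values the
#'   per-unit-exposure beta shift `delta`.
#' @param noise_sd SD of the logit-scale methylation noise (positive).
#' @param baseline_range range of per-CpG baseline mean beta values.
#' @param cell_fraction_means,cell_fraction_concentration Dirichlet mean and
#'   concentration for the six leukocyte fractions.
#' @param missing_rate fraction of beta values set missing at random.
#' @param seed integer master seed; stage-level substreams are derived from it
#'   so identical seeds give bit-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples, n_genes,
                       cpgs_per_gene = c(2L, 8L),
                       within_gene_correlation = 0.3,
                       exposure_model = exposure_zero_inflated(),
                       n_candidate_covariates = 4L,
                       effect_genes = numeric(0),
                       noise_sd = 0.4,
                       baseline_range = c(0.2, 0.8),
                       cell_fraction_means = c(CD8T = 0.09, CD4T = 0.14,
                                               NK = 0.04, Bcell = 0.09,
                                               Mono = 0.07, Gran = 0.57),
                       cell_fraction_concentration = 60,
                       missing_rate = 0,
                       seed = 1L) {
  err <- function(...) stop("invalid simulation configuration: ", ...,
                            call. = FALSE)
  if (n_samples < 2 || n_genes < 1) err("need n_samples >= 2, n_genes >= 1")
  cpgs_per_gene <- as.integer(cpgs_per_gene)
  if (length(cpgs_per_gene) != 2L || any(cpgs_per_gene < 1) ||
      cpgs_per_gene[1] > cpgs_per_gene[2]) {
    err("cpgs_per_gene must be an increasing positive integer pair")
  }
  rho <- within_gene_correlation
  if (!is.numeric(rho) || rho < 0 || rho >= 1) err("rho must lie in [0, 1)")
  if (!is.list(exposure_model) ||
      !exposure_model$type %in% c("continuous_zero_inflated", "categorical3")) {
    err("unknown exposure model")
  }
  if (exposure_model$type == "categorical3" &&
      (any(exposure_model$probs < 0) ||
       abs(sum(exposure_model$probs) - 1) > 1e-8)) {
    err("categorical probabilities must be in [0,1] and sum to 1")
  }
  if (noise_sd <= 0) err("noise_sd must be positive")
  if (missing_rate < 0 || missing_rate >= 1) err("missing_rate in [0, 1)")
  if (length(effect_genes)) {
    if (is.null(names(effect_genes))) err("effect_genes must be named")
    bad <- setdiff(names(effect_genes), gene_ids(n_genes))
    if (length(bad)) err("unknown effect gene(s): ",
                         paste(bad, collapse = ", "))
  }
  fr <- cell_fraction_means
  if (any(fr <= 0)) err("cell fraction means must be positive")
  fr <- fr / sum(fr)
  if (abs(seed) > 2^31 - 100) err("seed too large")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 cpgs_per_gene = cpgs_per_gene,
                 within_gene_correlation = rho,
                 exposure_model = exposure_model,
                 n_candidate_covariates = as.integer(n_candidate_covariates),
                 effect_genes = effect_genes,
                 noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 cell_fraction_means = fr,
                 cell_fraction_concentration = cell_fraction_concentration,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene identifiers used by the generator
#'
#' @param n number of genes.
#' @return Character vector `GENE00001 ...`.
#' @export
gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))

# Dirichlet draws via normalized gammas
rdirichlet_ <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

draw_exposure_ <- function(model, n) {
  if (model$type == "continuous_zero_inflated") {
    detected <- rbinom(n, 1L, 1 - model$p_zero)
    sdlog <- sqrt(log(1 + (model$sd_pos / model$mean_pos)^2))
    meanlog <- log(model$mean_pos) - sdlog^2 / 2
    pos <- rlnorm(n, meanlog, sdlog)
    list(exposure = detected * pos, label = NULL)
  } else {
    lev <- names(model$probs)
    lab <- sample(lev, n, replace = TRUE, prob = model$probs)
    list(exposure = encode_categorical_exposure(lab, lev), label = lab)
  }
}

draw_candidates_ <- function(n, k) {
  roster <- list(
    maternal_age = function() rnorm(n, 30, 4.5),
    education = function() factor(sample(c("lt_hs", "hs", "some_college",
                                           "college4"), n, replace = TRUE)),
    parity = function() factor(sample(c("0", "1", "2", "3plus"), n,
                                      replace = TRUE,
                                      prob = c(0.4, 0.35, 0.17, 0.08))),
    folate = function() rlnorm(n, log(10), 0.5),
    asthma = function() factor(sample(c("no", "yes"), n, replace = TRUE,
                                      prob = c(0.9, 0.1))),
    newborn_sex = function() factor(sample(c("F", "M"), n, replace = TRUE))
  )
  out <- list()
  for (j in seq_len(k)) {
    if (j <= length(roster)) {
      out[[names(roster)[j]]] <- roster[[j]]()
    } else {
      out[[sprintf("cov%02d", j)]] <- rnorm(n)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a synthetic methylation cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: beta values in `[0, 1]` with within-gene CpG correlation induced
#' by a one-factor Gaussian copula on the logit scale, Dirichlet cell-type
#' fractions, candidate covariates independent of the exposure, clean
#' per-sample QC fields, and exposure-proportional methylation shifts
#' implanted in the configured effect genes.
#'
#' @param config a [sim_config()].
#' @return A list of class `"synthetic_cohort"` with elements
#'   `methylation` (samples x CpGs beta matrix, `NA` = missing),
#'   `samples` (sample table with exposure, candidate covariates, cell
#'   fractions, and QC fields), `annotation` (CpG annotation data frame),
#'   `candidates` (names of the candidate covariate columns), and `truth`
#'   (effect genes and their `delta` values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  G <- config$n_genes
  genes <- gene_ids(G)

  set.seed(config$seed + 101L)
  expo <- draw_exposure_(config$exposure_model, n)

  set.seed(config$seed + 202L)
  cand <- draw_candidates_(n, config$n_candidate_covariates)

  set.seed(config$seed + 303L)
  frac <- rdirichlet_(n, config$cell_fraction_means *
                        config$cell_fraction_concentration)
  colnames(frac) <- names(config$cell_fraction_means)

  set.seed(config$seed + 404L)
  rng <- config$cpgs_per_gene
  m_g <- if (rng[1] == rng[2]) rep(rng[1], G) else
    sample(seq(rng[1], rng[2]), G, replace = TRUE)
  C <- sum(m_g)
  cpg_gene <- rep(genes, m_g)
  cpg_id <- sprintf("cg%08d", seq_len(C))
  chrom <- rep(sample(1:22, G, replace = TRUE), m_g)
  position <- unlist(lapply(seq_len(G), function(g) {
    start <- sample.int(1e8, 1L)
    start + sort(sample.int(5e4, m_g[g]))
  }), use.names = FALSE)

  mu <- qlogis(runif(C, config$baseline_range[1], config$baseline_range[2]))
  rho <- config$within_gene_correlation
  f <- matrix(rnorm(n * G), n, G)                    # shared gene factor
  e <- matrix(rnorm(n * C), n, C)                    # CpG-specific noise
  z <- sqrt(rho) * f[, rep(seq_len(G), m_g), drop = FALSE] +
    sqrt(1 - rho) * e
  beta <- plogis(sweep(config$noise_sd * z, 2, mu, `+`))

  if (length(config$effect_genes)) {
    for (g in names(config$effect_genes)) {
      idx <- which(cpg_gene == g)
      beta[, idx] <- beta[, idx] + config$effect_genes[[g]] * expo$exposure
    }
  }
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(sprintf("S%04d", seq_len(n)), cpg_id)

  if (config$missing_rate > 0) {
    set.seed(config$seed + 505L)
    beta[runif(length(beta)) < config$missing_rate] <- NA_real_
  }

  set.seed(config$seed + 606L)
  sex <- if ("newborn_sex" %in% names(cand)) {
    as.character(cand$newborn_sex)
  } else {
    sample(c("F", "M"), n, replace = TRUE)
  }
  samples <- data.frame(sample_id = rownames(beta),
                        exposure = expo$exposure,
                        stringsAsFactors = FALSE)
  if (!is.null(expo$label)) samples$exposure_label <- expo$label
  if (ncol(cand)) samples <- cbind(samples, cand)
  samples <- cbind(samples, as.data.frame(frac))
  samples$illumina_failed <- FALSE
  samples$mean_detection_p <- runif(n, 5e-4, 2e-3)
  samples$sex_reported <- sex
  samples$sex_predicted <- sex

  annotation <- data.frame(cpg_id = cpg_id,
                           chromosome = as.character(chrom),
                           position = position,
                           genes = cpg_gene,
                           is_control = FALSE,
                           stringsAsFactors = FALSE)

  structure(list(methylation = beta,
                 samples = samples,
                 annotation = annotation,
                 candidates = names(cand),
                 truth = list(effect_genes = config$effect_genes,
                              seed = config$seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples x %d CpGs (%d genes), %d effect gene(s)\n",
              nrow(x$methylation), ncol(x$methylation),
              length(unique(x$annotation$genes)),
              length(x$truth$effect_genes)))
  invisible(x)
}

#' Generate synthetic gene-set collections
#'
#' Draws gene sets over a gene universe, with a controllable shared core:
#' `overlap` is the fraction of the minimum set size that all sets have in
#' common (0 gives pairwise-disjoint sets, drawn without replacement from the
#' universe). With `include_filter_violations = TRUE` four extra sets are
#' appended, each engineered to fail exactly one of the downstream inclusion
#' criteria of [filter_gene_sets()]: one larger than 250 genes, one
#' non-human, one whose members carry no gene scores, and one from an
#' excluded category (C1).
#'
#' @param n_sets number of regular sets.
#' @param size_range integer range `c(min, max)` of set sizes.
#' @param overlap fraction in `[0, 1)` of the minimum size shared by all sets.
#' @param genes gene universe (character).
#' @param seed integer seed; the resulting GMT bytes are reproducible.
#' @param include_filter_violations append the four filter-violating sets.
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(n_sets, size_range, overlap = 0, genes,
                               seed = 1L, include_filter_violations = FALSE) {
  if (length(genes) == 0L) stop("empty gene universe")
  size_range <- as.integer(size_range)
  if (length(size_range) == 1L) size_range <- rep(size_range, 2L)
  if (size_range[2] > length(genes)) {
    stop("size_range exceeds the size of the gene universe")
  }
  stopifnot(overlap >= 0, overlap < 1)
  set.seed(seed)
  n_shared <- floor(overlap * size_range[1])
  shared <- if (n_shared > 0) sample(genes, n_shared) else character(0)
  pool <- setdiff(genes, shared)
  sets <- list()
  for (i in seq_len(n_sets)) {
    size <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(seq(size_range[1], size_range[2]), 1L)
    need <- size - n_shared
    if (need > length(pool)) {
      # exhausted the disjoint pool: draw the remainder from the universe
      extra <- sample(setdiff(genes, shared), need)
    } else {
      extra <- sample(pool, need)
      pool <- setdiff(pool, extra)
    }
    sets[[sprintf("SET_%03d", i)]] <- sort(c(shared, extra))
  }
  meta <- data.frame(name = names(sets),
                     contributor = "synthetic",
                     category = rep_len(c("C2", "C5", "C6", "C7"),
                                        length(sets)),
                     organism = "Homo sapiens",
                     stringsAsFactors = FALSE)
  if (include_filter_violations) {
    oversize <- sprintf("FILLER%05d", seq_len(251))
    viol <- list(VIOL_OVERSIZE = oversize,
                 VIOL_MOUSE = sample(genes, min(20L, length(genes))),
                 VIOL_NO_OVERLAP = sprintf("ABSENT%05d", 1:10),
                 VIOL_CATEGORY = sample(genes, min(10L, length(genes))))
    sets <- c(sets, viol)
    meta <- rbind(meta, data.frame(
      name = names(viol),
      contributor = "synthetic",
      category = c("C2", "C2", "C2", "C1"),
      organism = c("Homo sapiens", "Mus musculus",
                   "Homo sapiens", "Homo sapiens"),
      stringsAsFactors = FALSE))
  }
  gene_set_collection(sets, meta)
}
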