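# Shared fixtures and independent oracles used across test files.

# Brute-force evaluation of the BH step-up definition:
# q(i) = min_{j >= i} min(1, p(j) * m / j) on sorted p, restored to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Adjusted Rand index between two partitions (Hubert & Arabie).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small null cohort with a unit-scale continuous exposure (so effect sizes
# are interpretable as beta shifts per exposure unit).
quick_cohort <- function(n = 150, genes = 20, cpgs = c(2, 5), rho = 0.3,
                         effect = numeric(0), seed = 1, n_cand = 3,
                         exposure = exposure_zero_inflated(mean_pos = 1,
                                                           sd_pos = 0.5)) {
  generate_cohort(sim_config(
    n_samples = n, n_genes = genes, cpgs_per_gene = cpgs,
    within_gene_correlation = rho, exposure_model = exposure,
    n_candidate_covariates = n_cand, effect_genes = effect, seed = seed))
}

# Covariate selection with nothing selected and no forced fractions: the
# intercept-only design, handy for isolating the kernel-test algebra.
empty_selection <- function(samples) {
  sel <- select_covariates(samples, candidates = character(0),
                           forced = character(0), drop_fraction = NULL)
  sel
}

# Hand-built beta matrix fixture with named CpGs
beta_fixture <- function(n, cpg_ids, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * length(cpg_ids), 0.2, 0.8), n,
              dimnames = list(sprintf("S%03d", seq_len(n)), cpg_ids))
  m
}
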