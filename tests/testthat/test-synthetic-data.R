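test_that("identical seeds give bit-identical cohorts", {
  a <- quick_cohort(n = 60, genes = 8, seed = 11)
  b <- quick_cohort(n = 60, genes = 8, seed = 11)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotation, b$annotation)
})

test_that("betas stay in range and cell fractions sum to one", {
  coh <- quick_cohort(n = 80, genes = 10,
                      effect = c(GENE00001 = 0.3), seed = 2)
  expect_true(all(coh$methylation >= 0 & coh$methylation <= 1))
  fr <- as.matrix(coh$samples[, cell_fraction_names()])
  expect_true(all(fr >= 0))
  expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-12)
  # every CpG is annotated
  expect_true(all(colnames(coh$methylation) %in% coh$annotation$cpg_id))
})

test_that("with no implanted effects, exposure and gene-mean betas are uncorrelated", {
  coh <- quick_cohort(n = 400, genes = 25, seed = 3)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  r <- vapply(gm, function(cg) {
    cor(coh$samples$exposure,
        rowMeans(coh$methylation[, cg, drop = FALSE]))
  }, numeric(1))
  expect_true(all(abs(r) < 3 / sqrt(400)))
})

test_that("an implanted per-unit-exposure shift is recovered by OLS", {
  cfg <- sim_config(n_samples = 500, n_genes = 10,
                    within_gene_correlation = 0.3,
                    exposure_model = exposure_zero_inflated(mean_pos = 1,
                                                            sd_pos = 0.3),
                    baseline_range = c(0.3, 0.5),
                    effect_genes = c(GENE00001 = 0.2), seed = 4)
  coh <- generate_cohort(cfg)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  y <- rowMeans(coh$methylation[, gm$GENE00001, drop = FALSE])
  fit <- summary(lm(y ~ coh$samples$exposure))
  expect_lt(abs(fit$coefficients[2, 1] - 0.2), 2 * fit$coefficients[2, 2])
})

test_that("empirical within-gene CpG correlation converges to rho", {
  cfg <- sim_config(n_samples = 2000, n_genes = 15, cpgs_per_gene = c(4, 4),
                    within_gene_correlation = 0.4, seed = 5)
  coh <- generate_cohort(cfg)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  mean_pairwise <- vapply(gm, function(cg) {
    cm <- cor(coh$methylation[, cg, drop = FALSE])
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_lt(abs(mean(mean_pairwise) - 0.4), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(100, 10, within_gene_correlation = 1),
               "rho")
  expect_error(sim_config(100, 10,
                          exposure_model = list(type = "categorical3",
                                                probs = c(0.5, 0.2, 0.1))),
               "sum to 1")
  expect_error(sim_config(100, 10, effect_genes = c(NOPE = 0.1)),
               "unknown effect gene")
  expect_error(sim_config(100, 10, noise_sd = 0), "noise_sd")
})

test_that("gene-set generator controls overlap and is seed-stable on disk", {
  genes <- gene_ids(300)
  coll <- generate_gene_sets(2, c(10, 10), overlap = 0, genes = genes,
                             seed = 9)
  expect_length(intersect(coll$sets[[1]], coll$sets[[2]]), 0)

  f1 <- tempfile(fileext = ".gmt"); f2 <- tempfile(fileext = ".gmt")
  write_gmt(generate_gene_sets(5, c(5, 20), 0.3, genes, seed = 1), f1)
  write_gmt(generate_gene_sets(5, c(5, 20), 0.3, genes, seed = 1), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_gene_sets(2, c(5, 10), genes = character(0)),
               "empty gene universe")
  expect_error(generate_gene_sets(2, c(5, 400), genes = genes),
               "exceeds")
})

test_that("oversized sets all fail the 250-gene filter downstream", {
  genes <- gene_ids(300)
  coll <- generate_gene_sets(4, c(251, 251), overlap = 0.5, genes = genes,
                             seed = 10)
  kept <- filter_gene_sets(coll, scored_genes = genes)
  expect_length(kept, 0)
  expect_equal(unname(attr(kept, "filter_counts")["size"]), 4)
})

test_that("engineered violations each trip exactly one pathway filter", {
  genes <- gene_ids(50)
  coll <- generate_gene_sets(3, c(5, 10), 0, genes, seed = 2,
                             include_filter_violations = TRUE)
  kept <- filter_gene_sets(coll, scored_genes = genes)
  expect_setequal(names(kept), c("SET_001", "SET_002", "SET_003"))
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts[c("organism", "size", "no_overlap", "category")]),
               c(1, 1, 1, 1))
})
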