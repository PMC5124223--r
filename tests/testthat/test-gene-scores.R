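test_that("CpGs map to every annotated gene, with multi-gene CpGs shared", {
  m <- beta_fixture(5, sprintf("cg%02d", 1:4))
  ann <- data.frame(cpg_id = sprintf("cg%02d", 1:4),
                    genes = c("GENEA;GENEB", "GENEA", "", "GENEB"),
                    stringsAsFactors = FALSE)
  gm <- map_cpgs_to_genes(ann, m)
  expect_setequal(names(gm), c("GENEA", "GENEB"))
  expect_setequal(gm$GENEA, c("cg01", "cg02"))
  expect_setequal(gm$GENEB, c("cg01", "cg04"))

  ann$genes <- ""
  expect_length(map_cpgs_to_genes(ann, m), 0)
})

test_that("a shared CpG contributes to each gene's count on a 10-CpG fixture", {
  ids <- sprintf("cg%02d", 1:10)
  m <- beta_fixture(5, ids)
  genes <- c("G1", "G1", "G1", "G1;G2", "G2", "G2", "G2", "G3", "G3", "G3")
  ann <- data.frame(cpg_id = ids, genes = genes, stringsAsFactors = FALSE)
  gm <- map_cpgs_to_genes(ann, m)
  expect_equal(unname(lengths(gm)[c("G1", "G2", "G3")]), c(4, 4, 3))
})

test_that("the null model reduces to centering when no covariates exist", {
  set.seed(12)
  s <- data.frame(exposure = rexp(50))
  null <- fit_null_model(s, empty_selection(s))
  expect_equal(null$fitted, rep(mean(s$exposure), 50))
  expect_equal(null$residuals, s$exposure - mean(s$exposure))
})

test_that("residuals are orthogonal to the design", {
  coh <- quick_cohort(n = 120, genes = 5, seed = 13)
  sel <- select_covariates(coh$samples, coh$candidates)
  null <- fit_null_model(coh$samples, sel)
  expect_lt(max(abs(crossprod(null$X, null$residuals))), 1e-8)
})

test_that("an exposure fully explained by covariates yields Q = 0 and p = 1", {
  s <- data.frame(exposure = rexp(40), z = NA)
  s$z <- 2 * s$exposure
  sel <- empty_selection(s)
  sel$selected <- "z"
  expect_warning(null <- fit_null_model(s, sel), "zero residual variance")
  g <- beta_fixture(40, c("cg01", "cg02"))
  gs <- gene_score(null, g)
  expect_equal(gs$Q, 0, tolerance = 1e-18)
  expect_equal(gs$p_value, 1)
})

test_that("a single-CpG gene reduces exactly to the chi-square(1) score test", {
  set.seed(14)
  n <- 150
  s <- data.frame(exposure = rexp(n), age = rnorm(n))
  sel <- empty_selection(s)
  sel$selected <- "age"
  null <- fit_null_model(s, sel)
  g <- matrix(runif(n, 0.2, 0.8), n, 1, dimnames = list(NULL, "cg01"))
  gs <- gene_score(null, g)
  H_g <- null$X %*% null$XtXinv %*% crossprod(null$X, g)
  denom <- null$sigma2 * sum(g * (g - H_g))
  p_exact <- pchisq(sum(g * null$residuals)^2 / denom, df = 1,
                    lower.tail = FALSE)
  expect_equal(gs$p_value, p_exact, tolerance = 1e-10)
})

test_that("columns orthogonal to the residuals give Q = 0, p = 1", {
  set.seed(15)
  s <- data.frame(exposure = rexp(60))
  null <- fit_null_model(s, empty_selection(s))
  raw <- matrix(rnorm(60 * 2), 60, 2)
  g <- apply(raw, 2, function(col) resid(lm(col ~ null$residuals)))
  colnames(g) <- c("cg01", "cg02")
  gs <- gene_score(null, g)
  expect_lt(gs$Q, 1e-16)
  expect_equal(gs$p_value, 1)
})

test_that("an all-zero CpG matrix warns and returns p = 1", {
  s <- data.frame(exposure = rexp(30))
  null <- fit_null_model(s, empty_selection(s))
  expect_warning(gs <- gene_score(null, matrix(0, 30, 3)), "all-zero")
  expect_equal(gs$p_value, 1)
})

test_that("the score statistic ignores design-column contamination of the CpGs", {
  coh <- quick_cohort(n = 100, genes = 3, seed = 16)
  sel <- select_covariates(coh$samples, coh$candidates)
  null <- fit_null_model(coh$samples, sel)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  G <- coh$methylation[, gm[[1]], drop = FALSE]
  gs0 <- gene_score(null, G)
  G2 <- G + 3.7 * null$X[, 2]  # add a multiple of a design column
  gs1 <- gene_score(null, G2)
  expect_equal(gs1$Q, gs0$Q, tolerance = 1e-8)
  expect_equal(gs1$p_value, gs0$p_value, tolerance = 1e-8)
})

test_that("eigenvalues conserve the trace of the projected kernel", {
  coh <- quick_cohort(n = 80, genes = 2, cpgs = c(6, 6), seed = 17)
  sel <- select_covariates(coh$samples, coh$candidates)
  null <- fit_null_model(coh$samples, sel)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  G <- coh$methylation[, gm[[1]], drop = FALSE]
  gs <- gene_score(null, G)
  H_G <- null$X %*% null$XtXinv %*% crossprod(null$X, G)
  tr <- sum(diag(crossprod(G, G - H_G)))
  expect_equal(sum(gs$lambda), tr, tolerance = 1e-6)
})

test_that("permutation matrices are reproducible and duplicate genes identical", {
  coh <- quick_cohort(n = 60, genes = 4, seed = 18)
  sel <- select_covariates(coh$samples, coh$candidates)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  gm$DUPLICATE <- gm[[1]]  # second gene over the same CpGs
  nm1 <- permuted_gene_scores(coh$methylation, coh$samples, sel, gm,
                              B = 25, seed = 42)
  nm2 <- permuted_gene_scores(coh$methylation, coh$samples, sel, gm,
                              B = 25, seed = 42)
  expect_identical(nm1$p, nm2$p)
  expect_equal(nm1$p[, "DUPLICATE"], nm1$p[, names(gm)[1]])
  expect_true(all(nm1$p >= 0 & nm1$p <= 1))
  expect_error(permuted_gene_scores(coh$methylation, coh$samples, sel, gm,
                                    B = 0), "at least 1")
})

test_that("null permutation scores are uniform when methylation is independent", {
  coh <- quick_cohort(n = 150, genes = 8, cpgs = c(3, 5), seed = 19)
  sel <- select_covariates(coh$samples, coh$candidates)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  nm <- permuted_gene_scores(coh$methylation, coh$samples, sel, gm,
                             B = 500, seed = 20)
  ks <- apply(nm$p, 2, function(p) ks.test(p, "punif")$p.value)
  expect_true(all(ks > 0.01))
})

test_that("gene FDR annotation matches the BH oracle and flags at q < 0.25", {
  set.seed(22)
  scores <- data.frame(gene = gene_ids(20), n_markers = 3,
                       Q = 1, p_value = runif(20)^2)
  out <- gene_fdr(scores)
  expect_equal(out$q_value, bh_oracle(scores$p_value), tolerance = 1e-12)
  expect_equal(out$associated, out$q_value < 0.25)
  # rank-1 BH formula when the smallest scaled p wins every minimum
  p <- c(0.001, 0.5, 0.6, 0.7)
  expect_equal(gene_fdr(data.frame(gene = letters[1:4], n_markers = 1,
                                   Q = 1, p_value = p))$q_value[1],
               0.001 * 4)
  all_ones <- gene_fdr(data.frame(gene = letters[1:3], n_markers = 1,
                                  Q = 0, p_value = c(1, 1, 1)))
  expect_false(any(all_ones$associated))
})
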