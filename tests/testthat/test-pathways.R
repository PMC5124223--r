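test_that("GMT files round-trip exactly, with metadata", {
  genes <- gene_ids(40)
  coll <- generate_gene_sets(4, c(3, 10), 0.2, genes, seed = 30,
                             include_filter_violations = TRUE)
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_identical(back$sets, coll$sets)
  expect_identical(back$meta$organism, coll$meta$organism)
  expect_identical(back$meta$category, coll$meta$category)
})

test_that("toy and empty GMT files parse; malformed lines name their number", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\torganism=Homo sapiens;category=C2\tG1\tG2",
               "SETB\tdesc\tG3"), path)
  coll <- read_gmt(path)
  expect_length(coll, 2)
  expect_equal(lengths(coll$sets), c(SETA = 2L, SETB = 1L))
  expect_equal(coll$meta$organism, c("Homo sapiens", NA))

  writeLines(character(0), path)
  expect_length(read_gmt(path), 0)

  writeLines(c("SETA\tdesc\tG1", "BROKEN\tdesc-only"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("the four inclusion criteria filter as specified, preserving order", {
  sets <- list(OK_SMALL = c("G1", "G2"),
               TOO_BIG = sprintf("B%03d", 1:251),
               MOUSE = c("G1", "G3"),
               UNSCORED = c("X1", "X2"),
               POSITIONAL = c("G1", "G4"),
               OK_BOUNDARY = c("X9", "G1"))
  meta <- data.frame(name = names(sets),
                     contributor = "t",
                     category = c("C2", "C5", "C2", "C7", "C1", "C2"),
                     organism = c(rep("Homo sapiens", 2), "Mus musculus",
                                  rep("Homo sapiens", 3)),
                     stringsAsFactors = FALSE)
  coll <- gene_set_collection(sets, meta)
  kept <- filter_gene_sets(coll, scored_genes = c("G1", "G2", "G4"))
  expect_identical(names(kept), c("OK_SMALL", "OK_BOUNDARY"))
  # boundary: exactly 250 genes passes
  sets250 <- list(AT_LIMIT = sprintf("B%03d", 1:250))
  coll250 <- gene_set_collection(sets250, data.frame(
    name = "AT_LIMIT", contributor = "t", category = "C2",
    organism = "Homo sapiens", stringsAsFactors = FALSE))
  expect_length(filter_gene_sets(coll250, scored_genes = "B001"), 1)
})

test_that("the Lancaster transform reduces to Fisher at uniform df 2", {
  set.seed(33)
  p <- runif(6)
  w <- lancaster_weights(letters[1:6])
  expect_equal(lancaster_statistic(p, w), -2 * sum(log(p)),
               tolerance = 1e-10)
  expect_equal(lancaster_statistic(0.5, 2), -2 * log(0.5), tolerance = 1e-6)
  expect_equal(lancaster_statistic(rep(1, 4), rep(2, 4)), 0,
               tolerance = 1e-10)
  expect_error(lancaster_statistic(numeric(0), numeric(0)), "no p-values")
})

test_that("the Lancaster statistic is strictly monotone in each p-value", {
  set.seed(34)
  p <- runif(5, 0.2, 0.8)
  w <- c(2, 2, 3, 1.5, 2)
  T0 <- lancaster_statistic(p, w)
  for (i in seq_along(p)) {
    p2 <- p
    p2[i] <- p[i] / 2
    expect_gt(lancaster_statistic(p2, w), T0)
  }
})

test_that("marker-proportional weights average 2 and scale with CpG counts", {
  w <- lancaster_weights(c("a", "b", "c"), "marker_proportional",
                         marker_counts = c(a = 2, b = 4, c = 6))
  expect_equal(mean(w), 2)
  expect_equal(unname(w["b"] / w["a"]), 2)
  expect_error(lancaster_weights("a", "marker_proportional"), "marker_counts")
})

test_that("moment matching recovers the independence limit of Fisher", {
  set.seed(35)
  k <- 6
  null_T <- rowSums(matrix(rchisq(20000 * k, df = 2), ncol = k))
  for (T_obs in c(8, 12, 20, 30)) {
    mm <- pathway_pvalue(T_obs, null_T)
    expect_lt(abs(mm$c_hat - 1), 0.05)
    expect_lt(abs(mm$f_hat - 2 * k) / (2 * k), 0.05)
    expect_lt(abs(mm$p_value -
                    pchisq(T_obs, df = 2 * k, lower.tail = FALSE)), 0.02)
  }
})

test_that("a null vector standardized to Fisher moments reproduces Fisher exactly", {
  set.seed(36)
  k <- 5
  z <- rchisq(500, df = 3)
  null_T <- 2 * k + (z - mean(z)) / sd(z) * sqrt(4 * k)
  for (T_obs in c(5, 10, 18)) {
    expect_equal(pathway_pvalue(T_obs, null_T)$p_value,
                 pchisq(T_obs, df = 2 * k, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("an observed statistic at the null mean sits at the chi-square mean", {
  set.seed(37)
  null_T <- rowSums(matrix(rchisq(5000 * 4, df = 2), ncol = 4))
  mm <- pathway_pvalue(mean(null_T), null_T)
  expect_equal(mm$p_value,
               pchisq(mm$f_hat, df = mm$f_hat, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("perfect inter-gene correlation collapses the effective df to 2", {
  set.seed(38)
  k <- 7
  null_T <- k * rchisq(20000, df = 2)  # all genes identical per permutation
  mm <- pathway_pvalue(10, null_T)
  expect_lt(abs(mm$f_hat - 2) / 2, 0.05)
  expect_lt(abs(mm$c_hat - k) / k, 0.05)
})

test_that("degenerate permutation nulls are rejected", {
  expect_error(pathway_pvalue(5, rep(3, 100)), "degenerate")
  expect_error(pathway_pvalue(5, rchisq(10, 2)), "at least 30")
})

test_that("Bonferroni adjustment reproduces tabulated products and clips at 1", {
  expect_equal(signif(bonferroni_adjust(3.01e-14, 5836), 3), 1.76e-10)
  expect_equal(signif(bonferroni_adjust(1.83e-08, 5836), 3), 0.000107)
  expect_equal(signif(bonferroni_adjust(6.48e-09, 5836), 3), 3.78e-05)
  expect_equal(signif(bonferroni_adjust(2.16e-09, 5836), 3), 1.26e-05)
  expect_equal(signif(bonferroni_adjust(5.90e-08, 5836), 3), 0.000344)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_error(bonferroni_adjust(1.5, 10), "\\[0, 1\\]")
})

test_that("pathway scores are invariant to member-gene order and n = 1 Bonferroni is identity", {
  coh <- quick_cohort(n = 100, genes = 10, seed = 39)
  sel <- select_covariates(coh$samples, coh$candidates)
  gm <- map_cpgs_to_genes(coh$annotation, coh$methylation)
  null <- fit_null_model(coh$samples, sel)
  scores <- score_genes(coh$methylation, null, gm)
  nm <- permuted_gene_scores(coh$methylation, coh$samples, sel, gm,
                             B = 120, seed = 40)
  members <- gene_ids(10)[3:8]
  mk_coll <- function(g) gene_set_collection(
    list(ONE = g),
    data.frame(name = "ONE", contributor = "t", category = "C2",
               organism = "Homo sapiens", stringsAsFactors = FALSE))
  s1 <- score_pathways(scores, nm, mk_coll(members))
  s2 <- score_pathways(scores, nm, mk_coll(rev(members)))
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
  expect_equal(s1$p_bonferroni, s1$p_value)  # single set tested
  expect_equal(s1$n_genes_overlap, 6)
})

test_that("moment-matched and rank-based permutation p-values agree", {
  set.seed(41)
  k <- 5
  B <- 400
  for (i in 1:10) {
    null_T <- rowSums(matrix(rchisq(B * k, df = 2), ncol = k))
    T_obs <- quantile(null_T, runif(1, 0.05, 0.95))
    p_mom <- pathway_pvalue(T_obs, null_T)$p_value
    p_emp <- mean(null_T > T_obs)
    expect_lt(abs(p_mom - p_emp), 2 / sqrt(B))
  }
})
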