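test_that("beta values follow M/(M+U+offset)", {
  expect_equal(compute_beta(matrix(0), matrix(0))[1, 1], 0)
  expect_equal(compute_beta(matrix(900), matrix(0))[1, 1], 0.9)
  expect_equal(compute_beta(matrix(100), matrix(100))[1, 1], 1 / 3,
               tolerance = 1e-12)
  expect_error(compute_beta(matrix(-1), matrix(5)), "negative")
  b <- compute_beta(matrix(c(NA, 10), 1), matrix(c(5, NA), 1))
  expect_true(all(is.na(b)))
})

test_that("beta is monotone increasing in M and decreasing in U", {
  M <- seq(0, 1000, by = 100)
  bM <- compute_beta(matrix(M, 1), matrix(200, 1, length(M)))
  expect_true(all(diff(as.numeric(bM)) > 0))
  U <- seq(0, 1000, by = 100)
  bU <- compute_beta(matrix(300, 1, length(U)), matrix(U, 1))
  expect_true(all(diff(as.numeric(bU)) < 0))
})

probe_fixture <- function() {
  ids <- sprintf("cg%02d", 1:10)
  m <- beta_fixture(10, ids, seed = 3)
  m[1:2, "cg07"] <- NA  # 20% missing
  ann <- data.frame(cpg_id = ids,
                    chromosome = c("1", "2", "X", "Y", "3", "4", "5", "6",
                                   "7", "8"),
                    position = 1:10 * 1000,
                    genes = "G1",
                    is_control = c(TRUE, TRUE, rep(FALSE, 8)),
                    stringsAsFactors = FALSE)
  list(m = m, ann = ann)
}

test_that("probe filters remove control, X, Y and high-missingness probes", {
  fx <- probe_fixture()
  out <- filter_probes(fx$m, fx$ann, max_missing = 0.10)
  expect_equal(ncol(out$methylation), 5)
  expect_equal(out$report$probes_removed,
               c(control = 2, chrX = 1, chrY = 1, missingness = 1))
  # conservation: removals + retained = input
  expect_equal(sum(out$report$probes_removed) + out$report$n_retained,
               out$report$n_input)
  # idempotence
  again <- filter_probes(out$methylation, fx$ann, max_missing = 0.10)
  expect_identical(again$methylation, out$methylation)
  expect_equal(sum(again$report$probes_removed), 0)
})

test_that("clean autosomal matrices pass through probe filtering unchanged", {
  ids <- sprintf("cg%02d", 1:6)
  m <- beta_fixture(8, ids)
  ann <- data.frame(cpg_id = ids, chromosome = "12", position = 1:6,
                    genes = "G", is_control = FALSE)
  out <- filter_probes(m, ann)
  expect_identical(out$methylation, m)
  expect_equal(sum(out$report$probes_removed), 0)
})

test_that("max_missing = 0 with one missing cell per probe empties the matrix", {
  ids <- sprintf("cg%02d", 1:4)
  m <- beta_fixture(6, ids)
  m[cbind(1:4, 1:4)] <- NA
  ann <- data.frame(cpg_id = ids, chromosome = "2", position = 1:4,
                    genes = "G", is_control = FALSE)
  out <- filter_probes(m, ann, max_missing = 0)
  expect_equal(ncol(out$methylation), 0)
  expect_equal(sum(out$report$probes_removed), 4)
})

test_that("removal precedence is control before chromosome before missingness", {
  ids <- c("cg01", "cg02")
  m <- beta_fixture(5, ids)
  m[, "cg01"] <- NA
  ann <- data.frame(cpg_id = ids, chromosome = c("X", "1"), position = 1:2,
                    genes = "G", is_control = c(TRUE, FALSE))
  out <- filter_probes(m, ann)
  expect_equal(unname(out$report$probes_removed["control"]), 1)
  expect_equal(unname(out$report$probes_removed["chrX"]), 0)
})

test_that("unannotated probes raise an error naming them", {
  ids <- c("cg01", "cg02")
  m <- beta_fixture(5, ids)
  ann <- data.frame(cpg_id = "cg01", chromosome = "1", position = 1,
                    genes = "G", is_control = FALSE)
  expect_error(filter_probes(m, ann), "cg02")
})

sample_fixture <- function(n = 20) {
  ids <- sprintf("cg%02d", 1:5)
  m <- beta_fixture(n, ids, seed = 4)
  samples <- data.frame(sample_id = sprintf("S%03d", 1:n),
                        illumina_failed = FALSE,
                        mean_detection_p = 0.001,
                        sex_reported = rep(c("F", "M"), length.out = n),
                        sex_predicted = rep(c("F", "M"), length.out = n),
                        stringsAsFactors = FALSE)
  list(m = m, samples = samples)
}

test_that("sample filters drop failed, poor-detection and sex-mismatch samples", {
  fx <- sample_fixture()
  clean <- filter_samples(fx$m, fx$samples)
  expect_identical(clean$methylation, fx$m)

  one_failed <- fx$samples
  one_failed$illumina_failed[7] <- TRUE
  out <- filter_samples(fx$m, one_failed)
  expect_equal(nrow(out$methylation), 19)
  expect_equal(unname(out$report$samples_removed["failed"]), 1)

  mismatch <- fx$samples
  mismatch$sex_predicted[c(2, 9, 15)] <- c("F", "M", "M")
  out <- filter_samples(fx$m, mismatch)
  expect_equal(nrow(out$methylation), 17)
  expect_equal(unname(out$report$samples_removed["sex_mismatch"]), 3)
})

test_that("the detection rule direction is configurable", {
  fx <- sample_fixture()
  bad <- fx$samples
  bad$mean_detection_p[3] <- 0.2  # poor signal
  out <- filter_samples(fx$m, bad)  # default flags high detection p
  expect_equal(unname(out$report$samples_removed["detection"]), 1)
  # literal low-side reading: every clean sample has detection p < 0.05
  out2 <- filter_samples(fx$m, bad, detection_direction = "flag_low")
  expect_equal(unname(out2$report$samples_removed["detection"]), 19)
})

test_that("missing QC fields raise an error", {
  fx <- sample_fixture()
  broken <- fx$samples
  broken$mean_detection_p <- NULL
  expect_error(filter_samples(fx$m, broken), "mean_detection_p")
})
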