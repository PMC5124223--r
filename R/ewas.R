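#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (`>= 1`).
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @examples
#' signif(bonferroni_threshold(473864), 3)  # 1.06e-07
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a positive count")
  }
  alpha / n_tests
}

#' Per-CpG linear-model association with the exposure
#'
#' For every CpG, ordinary least squares of the beta value on the exposure
#' plus the selected covariates and forced cell fractions. All CpGs share one
#' design matrix, so the fits reduce to a single QR decomposition; missing
#' betas are mean-imputed per CpG at fit time (default) or handled
#' complete-case per CpG.
#'
#' @param m beta matrix (samples x CpGs), QC-filtered.
#' @param samples sample table aligned with `m`.
#' @param selection a [select_covariates()] result.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param impute `"mean"` (default) or `"complete"`.
#' @return Data frame of class `"cpg_results"` with one row per CpG:
#'   `cpg_id`, `coefficient` (beta change per exposure unit), `std_error`,
#'   `p_value`, `signed_log_p` (`sign(coefficient) * -log10(p)`), and
#'   `significant` at the Bonferroni threshold for the number of CpGs tested
#'   (recorded in attributes `n_tests` and `threshold`).
#' @export
fit_cpg_associations <- function(m, samples, selection, alpha = 0.05,
                                 impute = c("mean", "complete")) {
  impute <- match.arg(impute)
  stopifnot(nrow(samples) == nrow(m))
  X <- cbind(build_design(samples, selection),
             exposure = samples[[selection$exposure]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]],
               collapse = ", "))
  }
  n <- nrow(X); pcol <- ncol(X); df <- n - pcol
  if (df < 2L) stop("too few samples for the design")
  j <- pcol  # exposure column
  vjj <- chol2inv(chol(crossprod(X)))[j, j]

  if (impute == "mean") {
    Y <- impute_col_means_(m)
    coefs <- qr.coef(qrX, Y)
    res <- Y - X %*% coefs
    sigma2 <- colSums(res^2) / df
    b <- coefs[j, ]
    se <- sqrt(sigma2 * vjj)
    dfv <- rep(df, ncol(m))
  } else {
    b <- se <- dfv <- numeric(ncol(m))
    for (k in seq_len(ncol(m))) {
      ok <- !is.na(m[, k])
      fit <- lm.fit(X[ok, , drop = FALSE], m[ok, k])
      r <- fit$residuals
      dfv[k] <- sum(ok) - pcol
      s2 <- sum(r^2) / dfv[k]
      v <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))[j, j]
      b[k] <- fit$coefficients[j]
      se[k] <- sqrt(s2 * v)
    }
  }
  tstat <- b / se
  p <- 2 * pt(-abs(tstat), dfv)
  thr <- bonferroni_threshold(ncol(m), alpha)
  out <- data.frame(cpg_id = colnames(m),
                    coefficient = unname(b),
                    std_error = unname(se),
                    p_value = unname(p),
                    signed_log_p = unname(sign(b) * -log10(p)),
                    significant = unname(p < thr),
                    stringsAsFactors = FALSE)
  attr(out, "n_tests") <- ncol(m)
  attr(out, "threshold") <- thr
  class(out) <- c("cpg_results", "data.frame")
  out
}

chrom_order_ <- function(chrom) {
  chrom <- norm_chrom_(chrom)
  match(chrom, c(as.character(1:22), "X", "Y"))
}

#' Manhattan-ready table of per-CpG results
#'
#' Annotated results ordered by chromosome then position, with signed
#' `-log10(p)` and gene labels on genome-wide-significant rows.
#'
#' @param results a [fit_cpg_associations()] result.
#' @param ann CpG annotation data frame.
#' @param threshold significance threshold on the raw p-value (defaults to
#'   the Bonferroni threshold recorded in `results`).
#' @return Data frame with `cpg_id`, `chromosome`, `position`, `genes`,
#'   `coefficient`, `p_value`, `signed_log_p`, `significant`, `gene_label`.
#' @export
manhattan_table <- function(results, ann, threshold = attr(results, "threshold")) {
  idx <- match(results$cpg_id, ann$cpg_id)
  if (anyNA(idx)) stop("unannotated CpG(s) in results")
  out <- data.frame(cpg_id = results$cpg_id,
                    chromosome = norm_chrom_(ann$chromosome[idx]),
                    position = ann$position[idx],
                    genes = ann$genes[idx],
                    coefficient = results$coefficient,
                    p_value = results$p_value,
                    signed_log_p = results$signed_log_p,
                    significant = results$p_value < threshold,
                    stringsAsFactors = FALSE)
  out$gene_label <- ifelse(out$significant, out$genes, "")
  out[order(chrom_order_(out$chromosome), out$position), , drop = FALSE]
}
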