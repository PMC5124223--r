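#' Map CpGs to genes
#'
#' Builds the gene -> CpG map from the annotation. A CpG annotated to several
#' genes (semicolon- or comma-separated symbols) contributes to each of them;
#' CpGs without a gene symbol are excluded from gene-level analysis (but
#' remain available to the per-CpG analysis).
#'
#' @param ann annotation data frame (`cpg_id`, `genes`, ...).
#' @param m beta matrix whose column names define the CpGs in play.
#' @return Named list: gene symbol -> character vector of CpG ids, ordered as
#'   in the matrix. Genes with zero CpGs are absent.
#' @export
map_cpgs_to_genes <- function(ann, m) {
  cpgs <- colnames(m)
  ann <- ann[match(cpgs, ann$cpg_id), , drop = FALSE]
  genes_field <- as.character(ann$genes)
  genes_field[is.na(genes_field)] <- ""
  toks <- strsplit(genes_field, "[;,]")
  nrep <- lengths(toks)
  long <- data.frame(cpg = rep(cpgs, nrep),
                     gene = trimws(unlist(toks, use.names = FALSE)),
                     stringsAsFactors = FALSE)
  long <- long[nzchar(long$gene), , drop = FALSE]
  if (!nrow(long)) return(structure(list(), names = character(0)))
  split(long$cpg, long$gene)
}

#' Null model for the kernel score test
#'
#' Ordinary least squares of the exposure on the intercept, the selected
#' covariates and the forced cell fractions (minus the dropped compartment).
#' The gene's CpG matrix then plays the variant-set role of a
#' variance-component score test against this null.
#'
#' @param samples sample table.
#' @param selection a [select_covariates()] result.
#' @return Object of class `"kernel_null_model"`: design `X`, `residuals`,
#'   `sigma2` (`= r'r / (n - p)`), `fitted`, and `XtXinv`.
#' @export
fit_null_model <- function(samples, selection) {
  X <- build_design(samples, selection)
  y <- samples[[selection$exposure]]
  stopifnot(is.numeric(y), !anyNA(y))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient null-model design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]],
               collapse = ", "))
  }
  fitted <- qr.fitted(qrX, y)
  r <- y - fitted
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(r^2) / (n - p)
  degenerate <- sigma2 <= 1e-12 * (sum(y^2) / n + 1e-300)
  if (degenerate) {
    warning("exposure fully explained by covariates: zero residual variance")
  }
  structure(list(X = X, residuals = r, fitted = fitted, sigma2 = sigma2,
                 degenerate = degenerate,
                 XtXinv = chol2inv(chol(crossprod(X))), n = n, p = p),
            class = "kernel_null_model")
}

# eigenvalues of G'(I - H)G given precomputed G'G and G'X
gene_lambda_ <- function(GtG, GtX, XtXinv) {
  A <- GtG - GtX %*% XtXinv %*% t(GtX)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam[lam > 1e-10 * max(lam, 0)]
}

#' Variance-component kernel score test for one gene
#'
#' Score statistic `Q = r' G G' r` with the unweighted linear kernel over the
#' gene's raw CpG matrix `G`; under the null `Q / sigma2` is distributed as
#' `sum_j lambda_j chi-square(1)` with `lambda_j` the eigenvalues of
#' `G'(I - H)G`, and the tail probability is evaluated by
#' [chisq_mixture_pvalue()]. The `(I - H)` projection contains the intercept,
#' so the test is invariant to column mean shifts of `G`.
#'
#' @param null a [fit_null_model()].
#' @param G samples x CpGs beta submatrix for one gene (missing values are
#'   mean-imputed per CpG).
#' @return List of class `"gene_score"`: `n_markers`, `Q`, `lambda`,
#'   `p_value`.
#' @export
gene_score <- function(null, G) {
  stopifnot(inherits(null, "kernel_null_model"))
  G <- as.matrix(G)
  if (ncol(G) < 1L) stop("gene with zero CpG columns")
  if (nrow(G) != null$n) stop("G rows must match the null-model samples")
  G <- impute_col_means_(G)
  if (all(G == 0)) {
    warning("all-zero CpG matrix; p = 1")
    return(structure(list(n_markers = ncol(G), Q = 0,
                          lambda = numeric(0), p_value = 1),
                     class = "gene_score"))
  }
  u <- crossprod(G, null$residuals)
  Q <- sum(u^2)
  lam <- gene_lambda_(crossprod(G), crossprod(G, null$X), null$XtXinv)
  p <- if (length(lam) == 0L || Q <= 0 || isTRUE(null$degenerate)) 1 else
    as.numeric(chisq_mixture_pvalue(Q / null$sigma2, lam))
  structure(list(n_markers = ncol(G), Q = Q, lambda = lam, p_value = p),
            class = "gene_score")
}

#' Gene scores for every mapped gene
#'
#' @param m beta matrix.
#' @param null a [fit_null_model()].
#' @param gene_map a [map_cpgs_to_genes()] result.
#' @return Data frame with `gene`, `n_markers`, `Q`, `p_value`.
#' @export
score_genes <- function(m, null, gene_map) {
  rows <- lapply(names(gene_map), function(g) {
    gs <- gene_score(null, m[, gene_map[[g]], drop = FALSE])
    data.frame(gene = g, n_markers = gs$n_markers, Q = gs$Q,
               p_value = gs$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation null matrix of gene p-values
#'
#' For each permutation, one uniform random permutation is applied jointly to
#' the exposure and all covariate rows (methylation fixed), the null model is
#' refit, and every gene's kernel-test p-value is recomputed. The resulting
#' `B x G` matrix carries the inter-gene correlation structure and is the
#' null reference for the pathway-level combination.
#'
#' Joint shuffling preserves the exposure-covariate association (the internal
#' structure of the null model) while severing all links to methylation.
#' Because the permuted design satisfies `X_b'X_b = X'X`, the refit residuals
#' are exactly the permuted residuals and the residual variance is unchanged;
#' the eigenvalues of `G'(I - H_b)G` are recomputed per gene and permutation.
#'
#' @param m beta matrix.
#' @param samples sample table.
#' @param selection a [select_covariates()] result.
#' @param gene_map a [map_cpgs_to_genes()] result.
#' @param B number of permutations (default 1000).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return Object of class `"null_score_matrix"`: list with `p` (`B x G`
#'   matrix, columns named by gene), `B`, `seed`.
#' @export
permuted_gene_scores <- function(m, samples, selection, gene_map,
                                 B = 1000L, seed = 1L) {
  if (B < 1L) stop("B must be at least 1")
  null <- fit_null_model(samples, selection)
  X <- null$X
  r <- null$residuals
  genes <- names(gene_map)
  cpgs <- unique(unlist(gene_map, use.names = FALSE))
  bigG <- impute_col_means_(m[, cpgs, drop = FALSE])
  idx <- lapply(gene_map, function(cg) match(cg, cpgs))
  GtG <- lapply(idx, function(i) crossprod(bigG[, i, drop = FALSE]))

  P <- matrix(NA_real_, B, length(genes), dimnames = list(NULL, genes))
  set.seed(seed)
  n <- nrow(X)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    U <- crossprod(bigG, cbind(r[perm], X[perm, , drop = FALSE]))
    for (g in seq_along(genes)) {
      i <- idx[[g]]
      Q <- sum(U[i, 1L]^2)
      lam <- gene_lambda_(GtG[[g]], U[i, -1L, drop = FALSE], null$XtXinv)
      P[b, g] <- if (length(lam) == 0L || Q <= 0) 1 else
        as.numeric(chisq_mixture_pvalue(Q / null$sigma2, lam))
    }
  }
  structure(list(p = P, B = B, seed = seed), class = "null_score_matrix")
}

#' @export
print.null_score_matrix <- function(x, ...) {
  cat(sprintf("null score matrix: %d permutations x %d genes (seed %d)\n",
              x$B, ncol(x$p), x$seed))
  invisible(x)
}

#' Gene-level FDR annotation
#'
#' BH q-values across all tested genes, flagging genes associated at
#' `q < q_threshold` (default 0.25).
#'
#' @param scores data frame from [score_genes()].
#' @param q_threshold FDR threshold.
#' @return `scores` with `q_value` and `associated` columns appended.
#' @export
gene_fdr <- function(scores, q_threshold = 0.25) {
  scores$q_value <- bh_adjust(scores$p_value)
  scores$associated <- scores$q_value < q_threshold
  scores
}
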