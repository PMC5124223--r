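#' Filter gene sets for pathway analysis
#'
#' Keeps exactly the sets that pass all four inclusion criteria, in stable
#' input order: (1) organism is *Homo sapiens*; (2) at most `max_size` member
#' genes; (3) at least one member gene carries a gene score; (4) the category
#' is not among the excluded collections (positional C1, motif C3,
#' computational C4 by default).
#'
#' @param coll a [gene_set_collection()] with organism/category metadata.
#' @param scored_genes character vector of genes with available gene scores.
#' @param max_size maximum pathway size (250).
#' @param organism required organism label.
#' @param excluded_categories category codes to drop.
#' @return The filtered collection; attribute `"filter_counts"` records how
#'   many sets each criterion removed (first failing criterion, in the order
#'   organism, size, overlap, category).
#' @export
filter_gene_sets <- function(coll, scored_genes, max_size = 250,
                             organism = "Homo sapiens",
                             excluded_categories = c("C1", "C3", "C4")) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (anyNA(coll$meta$organism) || anyNA(coll$meta$category)) {
    stop("organism/category metadata required for gene-set filtering")
  }
  fail <- rep(NA_character_, length(coll))
  fail[coll$meta$category %in% excluded_categories] <- "category"
  overlap0 <- vapply(coll$sets, function(g) !any(g %in% scored_genes),
                     logical(1))
  fail[is.na(fail) & overlap0] <- "no_overlap"
  fail[lengths(coll$sets) > max_size] <- "size"
  fail[coll$meta$organism != organism] <- "organism"
  keep <- which(is.na(fail))
  out <- coll[keep]
  attr(out, "filter_counts") <- c(
    organism = sum(fail == "organism", na.rm = TRUE),
    size = sum(fail == "size", na.rm = TRUE),
    no_overlap = sum(fail == "no_overlap", na.rm = TRUE),
    category = sum(fail == "category", na.rm = TRUE))
  out
}

#' Lancaster degrees-of-freedom weights
#'
#' `uniform_df2` assigns every gene 2 degrees of freedom, which makes the
#' Lancaster transform coincide with Fisher's `-2 log p`. `marker_proportional`
#' makes a gene's degrees of freedom proportional to its CpG count,
#' normalized so the mean weight is 2.
#'
#' @param genes character vector of gene symbols.
#' @param scheme weighting scheme.
#' @param marker_counts named CpG counts per gene (required for
#'   `marker_proportional`).
#' @return Named positive weights, one per gene.
#' @export
lancaster_weights <- function(genes,
                              scheme = c("uniform_df2", "marker_proportional"),
                              marker_counts = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "uniform_df2") {
    return(setNames(rep(2, length(genes)), genes))
  }
  if (is.null(marker_counts)) stop("marker_counts required")
  cnt <- marker_counts[genes]
  if (anyNA(cnt)) stop("marker_counts missing for some genes")
  setNames(as.numeric(cnt) / mean(cnt) * 2, genes)
}

clip_p_ <- function(p) pmin(pmax(p, 1e-16), 1 - 1e-16)

#' Lancaster combination statistic
#'
#' `T = sum_i F^{-1}(p_i; w_i)` where `F^{-1}(.; w)` is the upper-tail
#' chi-square quantile with `w` degrees of freedom. With all `w_i = 2` this
#' is Fisher's `-2 sum log p_i`. p-values are clipped to
#' `[1e-16, 1 - 1e-16]` before the transform.
#'
#' @param p_values gene p-values in `(0, 1]`.
#' @param weights positive degrees of freedom, one per p-value (matched by
#'   name when both are named).
#' @return The scalar statistic `T >= 0`.
#' @export
lancaster_statistic <- function(p_values, weights) {
  if (length(p_values) == 0L) stop("no p-values to combine")
  if (!is.null(names(p_values)) && !is.null(names(weights))) {
    weights <- weights[names(p_values)]
  }
  stopifnot(length(weights) == length(p_values), all(weights > 0))
  sum(qchisq(clip_p_(p_values), df = weights, lower.tail = FALSE))
}

# scaled chi-square tail: P(c * X_f > T)
scaled_chisq_pvalue_ <- function(T_obs, c_hat, f_hat) {
  pchisq(T_obs / c_hat, df = f_hat, lower.tail = FALSE)
}

#' Pathway p-value from a permutation null of the Lancaster statistic
#'
#' Matches the first two moments of the permutation-null statistics with a
#' scaled chi-square: with `m = mean(null_T)` and `v = var(null_T)`
#' (Bessel-corrected), `c_hat = v / (2 m)`, `f_hat = 2 m^2 / v`, and
#' `p = P(chi-square(f_hat) > T_obs / c_hat)`. For independent genes with
#' `w_i = 2` this recovers Fisher's chi-square tail (`c_hat -> 1`,
#' `f_hat -> 2k`); correlation among genes inflates `c_hat` and deflates
#' `f_hat`.
#'
#' @param T_obs observed Lancaster statistic.
#' @param null_T vector of null statistics from the permutation matrix
#'   (length `>= 30`).
#' @return List with `p_value`, `c_hat`, `f_hat`.
#' @export
pathway_pvalue <- function(T_obs, null_T) {
  if (length(null_T) < 30L) stop("need at least 30 permutation null values")
  m <- mean(null_T)
  v <- var(null_T)
  if (!is.finite(v) || v <= 0) stop("degenerate permutation null (zero variance)")
  c_hat <- v / (2 * m)
  f_hat <- 2 * m^2 / v
  list(p_value = scaled_chisq_pvalue_(T_obs, c_hat, f_hat),
       c_hat = c_hat, f_hat = f_hat)
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param n number of tests.
#' @return `min(1, p * n)`, vectorized over `p`.
#' @examples
#' bonferroni_adjust(3.01e-14, 5836)  # 1.76e-10
#' @export
bonferroni_adjust <- function(p, n) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (n < 1) stop("n must be a positive count")
  pmin(1, p * n)
}

#' Pathway scores by correlated Lancaster combination
#'
#' For each (already filtered) gene set: the overlap genes are those members
#' with a gene score; the observed statistic combines their p-values via
#' [lancaster_statistic()]; the identical transform applied to each row of
#' the permutation null matrix (restricted to the same overlap genes) yields
#' the null statistics whose moments calibrate the scaled chi-square tail.
#' Bonferroni adjustment is over the number of sets tested.
#'
#' @param gene_scores data frame with `gene`, `p_value` (and `n_markers` when
#'   `weights_scheme = "marker_proportional"`).
#' @param null_matrix a [permuted_gene_scores()] result covering the scored
#'   genes.
#' @param coll filtered [gene_set_collection()].
#' @param weights_scheme see [lancaster_weights()].
#' @param alpha significance level applied after Bonferroni adjustment.
#' @return Data frame with one row per set: `name`, `contributor`,
#'   `category`, `n_genes_pathway`, `n_genes_overlap`, `T_obs`, `c_hat`,
#'   `f_hat`, `p_value`, `p_bonferroni`, `significant`.
#' @export
score_pathways <- function(gene_scores, null_matrix, coll,
                           weights_scheme = c("uniform_df2",
                                              "marker_proportional"),
                           alpha = 0.05) {
  weights_scheme <- match.arg(weights_scheme)
  stopifnot(inherits(coll, "gene_set_collection"),
            inherits(null_matrix, "null_score_matrix"))
  scored <- setNames(gene_scores$p_value, gene_scores$gene)
  marker_counts <- if (weights_scheme == "marker_proportional") {
    setNames(gene_scores$n_markers, gene_scores$gene)
  }
  n_sets <- length(coll)
  rows <- lapply(seq_len(n_sets), function(i) {
    members <- coll$sets[[i]]
    overlap <- members[members %in% names(scored)]
    if (!length(overlap)) {
      stop(sprintf("gene set '%s' has no scored genes; filter the collection first",
                   names(coll$sets)[i]))
    }
    missing_null <- setdiff(overlap, colnames(null_matrix$p))
    if (length(missing_null)) {
      stop("null matrix lacks gene(s): ",
           paste(utils::head(missing_null, 5), collapse = ", "))
    }
    w <- lancaster_weights(overlap, weights_scheme, marker_counts)
    T_obs <- lancaster_statistic(scored[overlap], w)
    nullp <- clip_p_(null_matrix$p[, overlap, drop = FALSE])
    null_T <- rowSums(matrix(qchisq(nullp, df = rep(w, each = nrow(nullp)),
                                    lower.tail = FALSE),
                             nrow = nrow(nullp)))
    mm <- pathway_pvalue(T_obs, null_T)
    data.frame(name = names(coll$sets)[i],
               contributor = coll$meta$contributor[i],
               category = coll$meta$category[i],
               n_genes_pathway = length(members),
               n_genes_overlap = length(overlap),
               T_obs = T_obs, c_hat = mm$c_hat, f_hat = mm$f_hat,
               p_value = mm$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_value, n_sets)
  out$significant <- out$p_value < alpha / n_sets
  attr(out, "n_sets_tested") <- n_sets
  out
}
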