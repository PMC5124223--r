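#' Encode the three-category smoking exposure as an ordinal dose
#'
#' `none / stopped / throughout` map to 0 / 1 / 2. The ordinal coding gives
#' the continuous-outcome kernel test a single dose-ordered exposure value.
#'
#' @param categories character vector of per-sample labels.
#' @param levels allowed labels in dose order.
#' @return Numeric vector of 0/1/2 codes.
#' @examples
#' encode_categorical_exposure(c("none", "stopped", "throughout"))  # 0 1 2
#' @export
encode_categorical_exposure <- function(categories,
                                        levels = c("none", "stopped",
                                                   "throughout")) {
  idx <- match(as.character(categories), levels)
  if (anyNA(idx)) {
    stop("unknown exposure label(s): ",
         paste(unique(categories[is.na(idx)]), collapse = ", "))
  }
  as.numeric(idx - 1L)
}

#' Replicate discovery-significant pathways in an independent cohort
#'
#' Runs covariate selection independently in the replication cohort,
#' recomputes kernel-test gene scores only for genes occurring in the
#' discovery-significant sets, rebuilds the permutation null, and combines
#' the gene scores per set exactly as in discovery. BH q-values (and
#' Bonferroni) are computed across the testable discovery hits only — the
#' replication family is never the full collection. A hit whose member genes
#' are all absent from the replication data is recorded as untestable and
#' excluded from the FDR family with a warning.
#'
#' @param discovery_hits data frame of discovery-significant pathways (a
#'   subset of a [score_pathways()] result; only `name` is required).
#' @param coll [gene_set_collection()] containing at least the hit sets.
#' @param cohort2 replication cohort: list with `methylation`, `samples`,
#'   `annotation` and optionally `candidates` (e.g. a
#'   [generate_cohort()] result). A numeric `exposure` column is expected;
#'   apply [encode_categorical_exposure()] beforehand for categorical data.
#' @param candidates candidate covariate columns for the replication
#'   selection (defaults to `cohort2$candidates`).
#' @param B number of permutations for the replication null matrix.
#' @param seed integer seed for the permutations.
#' @param q_threshold replication FDR threshold (0.05).
#' @param weights_scheme see [lancaster_weights()].
#' @param covariate_q covariate-selection FDR threshold.
#' @return Data frame with one row per hit, in input order: `name`,
#'   `n_genes_overlap`, `p_value`, `q_value`, `p_bonferroni`, `testable`,
#'   `replicated`.
#' @export
replicate_pathways <- function(discovery_hits, coll, cohort2,
                               candidates = NULL, B = 1000L, seed = 1L,
                               q_threshold = 0.05,
                               weights_scheme = c("uniform_df2",
                                                  "marker_proportional"),
                               covariate_q = 0.1) {
  weights_scheme <- match.arg(weights_scheme)
  if (!nrow(discovery_hits)) stop("no discovery hits to replicate")
  hit_names <- discovery_hits$name
  missing_sets <- setdiff(hit_names, names(coll))
  if (length(missing_sets)) {
    stop("collection lacks hit set(s): ",
         paste(missing_sets, collapse = ", "))
  }
  if (is.null(candidates)) candidates <- cohort2$candidates
  if (is.null(candidates)) stop("candidate covariate names required")

  selection2 <- select_covariates(cohort2$samples, candidates,
                                  q_threshold = covariate_q)
  genes_needed <- unique(unlist(coll$sets[hit_names], use.names = FALSE))
  gene_map2 <- map_cpgs_to_genes(cohort2$annotation, cohort2$methylation)
  gene_map2 <- gene_map2[intersect(names(gene_map2), genes_needed)]
  if (!length(gene_map2)) {
    warning("no hit-set genes present in the replication cohort")
    return(data.frame(name = hit_names, n_genes_overlap = 0L,
                      p_value = NA_real_, q_value = NA_real_,
                      p_bonferroni = NA_real_, testable = FALSE,
                      replicated = FALSE, stringsAsFactors = FALSE))
  }
  null2 <- fit_null_model(cohort2$samples, selection2)
  scores2 <- score_genes(cohort2$methylation, null2, gene_map2)
  nullmat2 <- permuted_gene_scores(cohort2$methylation, cohort2$samples,
                                   selection2, gene_map2, B = B, seed = seed)
  scored <- setNames(scores2$p_value, scores2$gene)
  marker_counts <- setNames(scores2$n_markers, scores2$gene)

  p <- setNames(rep(NA_real_, length(hit_names)), hit_names)
  n_overlap <- setNames(integer(length(hit_names)), hit_names)
  for (s in hit_names) {
    overlap <- intersect(coll$sets[[s]], names(scored))
    n_overlap[s] <- length(overlap)
    if (!length(overlap)) next
    w <- lancaster_weights(overlap, weights_scheme,
                           if (weights_scheme == "marker_proportional")
                             marker_counts)
    T_obs <- lancaster_statistic(scored[overlap], w)
    nullp <- clip_p_(nullmat2$p[, overlap, drop = FALSE])
    null_T <- rowSums(matrix(qchisq(nullp, df = rep(w, each = nrow(nullp)),
                                    lower.tail = FALSE),
                             nrow = nrow(nullp)))
    p[s] <- pathway_pvalue(T_obs, null_T)$p_value
  }
  testable <- !is.na(p)
  if (any(!testable)) {
    warning(sprintf("%d pathway(s) untestable in the replication cohort (no scored genes); excluded from the FDR family",
                    sum(!testable)))
  }
  q <- bonf <- setNames(rep(NA_real_, length(p)), hit_names)
  if (any(testable)) {
    q[testable] <- bh_adjust(p[testable])
    bonf[testable] <- bonferroni_adjust(p[testable], sum(testable))
  }
  data.frame(name = hit_names,
             n_genes_overlap = unname(n_overlap),
             p_value = unname(p),
             q_value = unname(q),
             p_bonferroni = unname(bonf),
             testable = unname(testable),
             replicated = unname(testable & q < q_threshold),
             stringsAsFactors = FALSE)
}
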