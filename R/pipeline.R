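#' Pipeline configuration
#'
#' Collects every threshold of the workflow with its conventional default:
#' per-CpG family-wise alpha 0.05, gene FDR 0.25, pathway alpha 0.05 after
#' Bonferroni, replication FDR 0.05, covariate-screen FDR 0.1, probe
#' missingness 10%, maximum pathway size 250 genes, 1000 permutations.
#'
#' @param alpha_cpg per-CpG family-wise error rate.
#' @param gene_q gene-level FDR threshold.
#' @param pathway_alpha pathway significance level (after Bonferroni).
#' @param replication_q replication FDR threshold.
#' @param covariate_q covariate-selection FDR threshold.
#' @param max_missing probe missingness tolerance.
#' @param max_set_size largest admissible pathway.
#' @param B number of permutations for the null score matrix.
#' @param weights_scheme Lancaster weight scheme, see [lancaster_weights()].
#' @param k_clusters number of clusters for replicated pathways.
#' @param detection_direction sample detection-p rule direction, see
#'   [filter_samples()].
#' @param seed integer seed for the permutation streams.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha_cpg = 0.05, gene_q = 0.25,
                            pathway_alpha = 0.05, replication_q = 0.05,
                            covariate_q = 0.1, max_missing = 0.10,
                            max_set_size = 250, B = 1000L,
                            weights_scheme = "uniform_df2", k_clusters = 6L,
                            detection_direction = "flag_high", seed = 1L) {
  thr <- c(alpha_cpg = alpha_cpg, gene_q = gene_q,
           pathway_alpha = pathway_alpha, replication_q = replication_q,
           covariate_q = covariate_q, max_missing = max_missing)
  if (any(thr <= 0 | thr > 1)) stop("thresholds must lie in (0, 1]")
  if (B < 1L) stop("B must be at least 1")
  structure(list(alpha_cpg = alpha_cpg, gene_q = gene_q,
                 pathway_alpha = pathway_alpha,
                 replication_q = replication_q, covariate_q = covariate_q,
                 max_missing = max_missing, max_set_size = max_set_size,
                 B = as.integer(B), weights_scheme = weights_scheme,
                 k_clusters = as.integer(k_clusters),
                 detection_direction = detection_direction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the discovery analysis end to end
#'
#' Probe and sample QC, covariate selection, per-CpG association, gene
#' scores with the permutation null matrix, gene-set filtering and pathway
#' scores, in that order, on one cohort.
#'
#' @param cohort list with `methylation`, `samples`, `annotation`,
#'   `candidates` (e.g. a [generate_cohort()] result).
#' @param gene_sets a [gene_set_collection()].
#' @param config a [pipeline_config()].
#' @return List of class `"discovery_run"` with elements `qc`, `selection`,
#'   `cpg_results`, `manhattan`, `gene_scores`, `null_matrix`, `pathways`,
#'   `filtered_sets`, and a `manifest` of record counts and settings.
#' @export
run_discovery <- function(cohort, gene_sets, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  pf <- filter_probes(cohort$methylation, cohort$annotation,
                      max_missing = config$max_missing)
  sf <- filter_samples(pf$methylation, cohort$samples,
                       detection_direction = config$detection_direction)
  m <- sf$methylation
  samples <- sf$samples

  selection <- select_covariates(samples, cohort$candidates,
                                 q_threshold = config$covariate_q)
  cpg <- fit_cpg_associations(m, samples, selection, alpha = config$alpha_cpg)
  manhattan <- manhattan_table(cpg, cohort$annotation)

  gene_map <- map_cpgs_to_genes(cohort$annotation, m)
  null <- fit_null_model(samples, selection)
  scores <- gene_fdr(score_genes(m, null, gene_map), config$gene_q)
  null_matrix <- permuted_gene_scores(m, samples, selection, gene_map,
                                      B = config$B, seed = config$seed)

  filtered <- filter_gene_sets(gene_sets, scores$gene,
                               max_size = config$max_set_size)
  pathways <- if (length(filtered)) {
    score_pathways(scores, null_matrix, filtered,
                   weights_scheme = config$weights_scheme,
                   alpha = config$pathway_alpha)
  } else {
    warning("no gene sets pass the filters")
    NULL
  }

  manifest <- list(
    config = unclass(config),
    counts = list(
      samples_in = nrow(cohort$methylation),
      samples_tested = nrow(m),
      probes_in = ncol(cohort$methylation),
      cpgs_tested = ncol(m),
      probes_removed = as.list(pf$report$probes_removed),
      samples_removed = as.list(sf$report$samples_removed),
      genes_tested = nrow(scores),
      sets_in = length(gene_sets),
      sets_tested = length(filtered),
      cpg_significant = sum(cpg$significant),
      genes_associated = sum(scores$associated),
      pathways_significant = if (is.null(pathways)) 0L
                             else sum(pathways$significant)),
    selected_covariates = selection$selected,
    cpg_threshold = attr(cpg, "threshold"),
    pathway_threshold = if (length(filtered))
      bonferroni_threshold(length(filtered), config$pathway_alpha) else NA)

  structure(list(qc = list(probes = pf$report, samples = sf$report),
                 methylation = m, samples = samples,
                 selection = selection, cpg_results = cpg,
                 manhattan = manhattan, gene_map = gene_map,
                 gene_scores = scores, null_matrix = null_matrix,
                 filtered_sets = filtered, pathways = pathways,
                 manifest = manifest),
            class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf(paste0("discovery run: %d samples, %d CpGs, %d genes, %d sets tested\n",
                     "  significant: %d CpGs, %d genes (q<%.2f), %d pathways (Bonferroni)\n"),
              cts$samples_tested, cts$cpgs_tested, cts$genes_tested,
              cts$sets_tested, cts$cpg_significant, cts$genes_associated,
              x$manifest$config$gene_q, cts$pathways_significant))
  invisible(x)
}

#' Run the replication and clustering stages
#'
#' Replicates the discovery-significant pathways in an independent cohort
#' (see [replicate_pathways()]) and clusters the replicated pathways by gene
#' membership. With zero discovery-significant pathways the stage returns an
#' empty result cleanly; clustering is skipped (with a notice) when fewer
#' replicated pathways than clusters exist.
#'
#' @param discovery a [run_discovery()] result.
#' @param cohort2 replication cohort (as in [replicate_pathways()]).
#' @param gene_sets the same [gene_set_collection()] used at discovery.
#' @param config a [pipeline_config()] for the replication stage.
#' @return List of class `"replication_run"` with `replication` (per-hit
#'   table), `replicated_sets`, `membership`, `clusters`, `manifest`.
#' @export
run_replication <- function(discovery, cohort2, gene_sets,
                            config = pipeline_config()) {
  stopifnot(inherits(discovery, "discovery_run"),
            inherits(config, "pipeline_config"))
  if (is.null(discovery$pathways)) stop("discovery run has no pathway table")
  hits <- discovery$pathways[discovery$pathways$significant, , drop = FALSE]
  if (!nrow(hits)) {
    message("no discovery-significant pathways; nothing to replicate")
    empty <- data.frame(name = character(0), n_genes_overlap = integer(0),
                        p_value = numeric(0), q_value = numeric(0),
                        p_bonferroni = numeric(0), testable = logical(0),
                        replicated = logical(0))
    return(structure(list(replication = empty, replicated_sets = NULL,
                          membership = NULL, clusters = NULL,
                          manifest = list(n_hits = 0L, n_replicated = 0L)),
                     class = "replication_run"))
  }
  rep_tab <- replicate_pathways(hits, gene_sets, cohort2,
                                B = config$B, seed = config$seed,
                                q_threshold = config$replication_q,
                                weights_scheme = config$weights_scheme,
                                covariate_q = config$covariate_q)
  rep_names <- rep_tab$name[rep_tab$replicated]
  replicated_sets <- if (length(rep_names)) gene_sets[rep_names]
  membership <- clusters <- NULL
  if (length(rep_names) >= 2L) {
    membership <- membership_matrix(replicated_sets)
    if (length(rep_names) >= config$k_clusters) {
      clusters <- cluster_pathways(membership, k = config$k_clusters)
    } else {
      message(sprintf("only %d replicated pathways; skipping the %d-cluster cut",
                      length(rep_names), config$k_clusters))
    }
  }
  structure(list(replication = rep_tab, replicated_sets = replicated_sets,
                 membership = membership, clusters = clusters,
                 manifest = list(n_hits = nrow(hits),
                                 n_testable = sum(rep_tab$testable),
                                 n_replicated = length(rep_names),
                                 config = unclass(config))),
            class = "replication_run")
}

#' @export
print.replication_run <- function(x, ...) {
  cat(sprintf("replication run: %d hits, %d testable, %d replicated\n",
              x$manifest$n_hits, x$manifest$n_testable %||% 0L,
              x$manifest$n_replicated))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
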