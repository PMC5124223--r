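#' Write a synthetic cohort to plain-text files
#'
#' `methylation.tsv` (rows = CpGs, columns = samples), `samples.csv`,
#' `annotation.tsv`, and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- t(cohort$methylation)
  write.table(data.frame(cpg_id = rownames(meth), meth, check.names = FALSE),
              file.path(dir, "methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(cohort$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.table(cohort$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(effect_genes = as.list(cohort$truth$effect_genes),
                            seed = cohort$truth$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return A list shaped like a [generate_cohort()] result (without `truth`
#'   when `truth.json` is absent).
#' @export
read_cohort <- function(dir) {
  meth <- read.delim(file.path(dir, "methylation.tsv"), check.names = FALSE)
  m <- t(as.matrix(meth[, -1, drop = FALSE]))
  colnames(m) <- meth$cpg_id
  samples <- read.csv(file.path(dir, "samples.csv"), stringsAsFactors = FALSE)
  annotation <- read.delim(file.path(dir, "annotation.tsv"),
                           stringsAsFactors = FALSE)
  annotation$chromosome <- as.character(annotation$chromosome)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    list(effect_genes = unlist(tr$effect_genes), seed = tr$seed)
  }
  qc <- c("exposure", "exposure_label", "illumina_failed", "mean_detection_p",
          "sex_reported", "sex_predicted", "sample_id")
  structure(list(methylation = m, samples = samples, annotation = annotation,
                 candidates = setdiff(names(samples),
                                      c(qc, cell_fraction_names())),
                 truth = truth),
            class = "synthetic_cohort")
}

write_tsv_ <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write discovery-run artifacts
#'
#' Per-CpG results, Manhattan table, gene scores, pathway scores, the
#' permutation null matrix (TSV plus JSON sidecar), and the run manifest.
#'
#' @param run a [run_discovery()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_discovery <- function(run, dir) {
  stopifnot(inherits(run, "discovery_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(run$cpg_results, file.path(dir, "cpg_results.tsv"))
  write_tsv_(run$manhattan, file.path(dir, "manhattan.tsv"))
  write_tsv_(run$gene_scores, file.path(dir, "gene_scores.tsv"))
  if (!is.null(run$pathways)) {
    write_tsv_(run$pathways, file.path(dir, "pathway_scores.tsv"))
  }
  write_tsv_(as.data.frame(run$null_matrix$p, check.names = FALSE),
             file.path(dir, "null_score_matrix.tsv"))
  jsonlite::write_json(list(B = run$null_matrix$B,
                            seed = run$null_matrix$seed,
                            genes = colnames(run$null_matrix$p)),
                       file.path(dir, "null_score_matrix.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' Write replication-run artifacts
#'
#' Replication table, membership matrix, cluster labels, Newick tree, and
#' manifest (whichever exist for the run).
#'
#' @param run a [run_replication()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_replication <- function(run, dir) {
  stopifnot(inherits(run, "replication_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(run$replication, file.path(dir, "replication.tsv"))
  if (!is.null(run$membership)) {
    write_tsv_(data.frame(pathway = rownames(run$membership),
                          run$membership, check.names = FALSE),
               file.path(dir, "membership_matrix.tsv"))
  }
  if (!is.null(run$clusters)) {
    write_tsv_(data.frame(pathway = names(run$clusters$labels),
                          cluster = unname(run$clusters$labels)),
               file.path(dir, "cluster_labels.tsv"))
    cluster_newick(run$clusters, file.path(dir, "dendrogram.nwk"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
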