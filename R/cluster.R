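#' Binary gene-membership matrix of pathways
#'
#' Rows are pathways, columns the union of their member genes (sorted), and
#' entries are 1 when the pathway contains the gene.
#'
#' @param coll a [gene_set_collection()] with at least two sets.
#' @return Integer 0/1 matrix with pathway names as row names.
#' @export
membership_matrix <- function(coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (length(coll) < 2L) stop("need at least 2 pathways to tabulate")
  genes <- sort(unique(unlist(coll$sets, use.names = FALSE)))
  m <- vapply(coll$sets, function(g) as.integer(genes %in% g),
              integer(length(genes)))
  t(matrix(m, nrow = length(genes),
           dimnames = list(genes, names(coll$sets))))
}

#' Hierarchical clustering of pathways by gene membership
#'
#' Agglomerative clustering of the binary membership rows with Euclidean
#' distance and Ward linkage (Ward.D2 by default, the squared-distance
#' variance-minimizing update), cut into `k` groups.
#'
#' @param m a [membership_matrix()].
#' @param k number of clusters (default 6).
#' @param method `"ward.D2"` or the classic `"ward.D"` dialect.
#' @return Object of class `"pathway_clusters"`: list with `labels` (named
#'   cluster assignment in `1..k`), `hclust` (the merge tree), and `k`.
#' @export
cluster_pathways <- function(m, k = 6L, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (nrow(m) < k) stop(sprintf("cannot cut %d pathways into %d clusters",
                                nrow(m), k))
  hc <- hclust(dist(m, method = "euclidean"), method = method)
  labels <- cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc, k = k),
            class = "pathway_clusters")
}

#' @export
print.pathway_clusters <- function(x, ...) {
  cat(sprintf("pathway clustering: %d pathways in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Export a pathway dendrogram as a Newick tree
#'
#' @param clusters a [cluster_pathways()] result.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
cluster_newick <- function(clusters, path = NULL) {
  stopifnot(inherits(clusters, "pathway_clusters"))
  phy <- ape::as.phylo(clusters$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
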