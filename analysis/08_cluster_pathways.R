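#!/usr/bin/env Rscript
# Stage 8 — hierarchical clustering of replicated pathways by gene
# membership (binary matrix, Euclidean distance, Ward.D2), cut into up to
# six groups, with a Newick export of the dendrogram.

suppressPackageStartupMessages(library(methscore))

rep_tab <- read.delim("results/replication/replication.tsv",
                      stringsAsFactors = FALSE)
sets <- read_gmt("results/data/gene_sets.gmt")

replicated <- rep_tab$name[rep_tab$replicated]
if (length(replicated) < 2) {
  cat("fewer than two replicated pathways; nothing to cluster\n")
  quit(save = "no")
}
coll <- sets[replicated]
mm <- membership_matrix(coll)
k <- min(6L, nrow(mm))
cl <- cluster_pathways(mm, k = k)

write.table(data.frame(pathway = rownames(mm), mm, check.names = FALSE),
            "results/replication/membership_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(pathway = names(cl$labels),
                       cluster = unname(cl$labels)),
            "results/replication/cluster_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cluster_newick(cl, "results/replication/dendrogram.nwk")

print(cl)
for (g in seq_len(cl$k)) {
  cat(sprintf("  cluster %d: %s\n", g,
              paste(names(cl$labels)[cl$labels == g], collapse = ", ")))
}
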