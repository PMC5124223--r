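#!/usr/bin/env Rscript
# Stage 6 — gene-set filtering and correlated-Lancaster pathway scores.
#
# Sets must be human, at most 250 genes, overlap the scored genes, and come
# from an admissible category (positional, motif and computational
# collections excluded). Gene p-values combine by the df-2 Lancaster (Fisher)
# transform; the permutation null matrix supplies the moments of the
# scaled-chi-square null, so inter-gene correlation is respected. Bonferroni
# over the sets tested defines discovery significance.

suppressPackageStartupMessages(library(methscore))

sets <- read_gmt("results/data/gene_sets.gmt")
scores <- read.delim("results/discovery/gene_scores.tsv",
                     stringsAsFactors = FALSE)
nullp <- as.matrix(read.delim("results/discovery/null_score_matrix.tsv",
                              check.names = FALSE))
side <- jsonlite::read_json("results/discovery/null_score_matrix.json",
                            simplifyVector = TRUE)
colnames(nullp) <- side$genes
nullmat <- structure(list(p = nullp, B = side$B, seed = side$seed),
                     class = "null_score_matrix")

filtered <- filter_gene_sets(sets, scored_genes = scores$gene)
pathways <- score_pathways(scores, nullmat, filtered)

write.table(pathways, "results/discovery/pathway_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d/%d sets pass the four filters (removed: %s)\n",
            length(filtered), length(sets),
            paste(names(attr(filtered, "filter_counts")),
                  attr(filtered, "filter_counts"), sep = "=",
                  collapse = ", ")))
cat(sprintf("Bonferroni threshold %.3g; %d significant pathway(s)\n",
            bonferroni_threshold(length(filtered)),
            sum(pathways$significant)))
sig <- pathways[pathways$significant,
                c("name", "n_genes_overlap", "p_value", "p_bonferroni")]
print(sig, row.names = FALSE, digits = 3)
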