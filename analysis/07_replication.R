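#!/usr/bin/env Rscript
# Stage 7 — replication of discovery-significant pathways in the second
# cohort (three-category smoking exposure, ordinal 0/1/2).
#
# Covariate selection is re-run in the replication cohort; gene scores are
# computed only for genes in the discovery hits; BH q < 0.05 over the
# testable hits decides replication.

suppressPackageStartupMessages(library(methscore))

pathways <- read.delim("results/discovery/pathway_scores.tsv",
                       stringsAsFactors = FALSE)
sets <- read_gmt("results/data/gene_sets.gmt")
coh2 <- read_cohort("results/data/replication")

hits <- pathways[pathways$significant, , drop = FALSE]
dir.create("results/replication", showWarnings = FALSE, recursive = TRUE)
if (!nrow(hits)) {
  cat("no discovery-significant pathways; nothing to replicate\n")
  quit(save = "no")
}
rep_tab <- replicate_pathways(hits, sets, coh2, B = 400L,
                              seed = 20160107L, q_threshold = 0.05)
write.table(rep_tab, "results/replication/replication.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d discovery hits, %d testable, %d replicated at q < 0.05\n",
            nrow(rep_tab), sum(rep_tab$testable), sum(rep_tab$replicated)))
print(rep_tab[, c("name", "n_genes_overlap", "p_value", "q_value",
                  "replicated")], row.names = FALSE, digits = 3)
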