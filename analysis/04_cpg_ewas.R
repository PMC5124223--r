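#!/usr/bin/env Rscript
# Stage 4 — per-CpG linear-model association with cotinine.
#
# One OLS fit per CpG (beta ~ exposure + selected covariates + forced cell
# fractions), Bonferroni threshold over the CpGs actually tested, and a
# Manhattan-ready table ordered by genomic position with signed -log10 p.

suppressPackageStartupMessages(library(methscore))

coh <- read_cohort("results/data/discovery")
samples <- read.csv("results/discovery/samples_qc.csv",
                    stringsAsFactors = FALSE)
meth <- read.delim("results/discovery/methylation_qc.tsv",
                   check.names = FALSE)
m <- t(as.matrix(meth[, -1, drop = FALSE]))
colnames(m) <- meth$cpg_id
m <- m[samples$sample_id, , drop = FALSE]

sel <- select_covariates(samples, coh$candidates, q_threshold = 0.1)
res <- fit_cpg_associations(m, samples, sel)
man <- manhattan_table(res, coh$annotation)

write.table(res, "results/discovery/cpg_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(man, "results/discovery/manhattan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

thr <- attr(res, "threshold")
sig <- man[man$significant, , drop = FALSE]
cat(sprintf("%d CpGs tested; Bonferroni threshold %.3g; %d genome-wide significant\n",
            attr(res, "n_tests"), thr, nrow(sig)))
if (nrow(sig)) {
  cat("significant CpGs map to:",
      paste(sort(unique(sig$genes[nzchar(sig$genes)])), collapse = ", "),
      "\n")
}
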