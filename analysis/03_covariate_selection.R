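#!/usr/bin/env Rscript
# Stage 3 — FDR-screened covariate selection on the QC'd discovery cohort.
#
# Each candidate is regressed against the cotinine exposure; BH q < 0.1
# selects adjustment covariates. The six cell-type fractions are forced into
# every later design regardless (granulocytes dropped for identifiability).
# Under the simulation's null covariates, selections are rare false
# positives; the report records p, q and the decision per candidate.

suppressPackageStartupMessages(library(methscore))

samples <- read.csv("results/discovery/samples_qc.csv",
                    stringsAsFactors = FALSE)
coh <- read_cohort("results/data/discovery")
sel <- select_covariates(samples, coh$candidates, q_threshold = 0.1)

write.table(sel$table, "results/discovery/covariate_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(selected = sel$selected, forced = sel$forced,
                          drop_fraction = sel$drop_fraction,
                          q_threshold = sel$q_threshold),
                     "results/discovery/covariate_selection.json",
                     auto_unbox = TRUE)
print(sel)
print(sel$table, digits = 3)
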