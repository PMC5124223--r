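#!/usr/bin/env Rscript
# Stage 2 — probe- and sample-level QC on the discovery cohort.
#
# Control probes, X/Y probes and probes with >10% missing betas are removed
# (in that precedence), then failed samples, samples with a poor mean
# detection p-value, and sex mismatches. The filtered matrix and sample
# table feed every later stage.

suppressPackageStartupMessages(library(methscore))

coh <- read_cohort("results/data/discovery")
pf <- filter_probes(coh$methylation, coh$annotation, max_missing = 0.10)
sf <- filter_samples(pf$methylation, coh$samples)

dir.create("results/discovery", showWarnings = FALSE, recursive = TRUE)
meth <- t(sf$methylation)
write.table(data.frame(cpg_id = rownames(meth), meth, check.names = FALSE),
            "results/discovery/methylation_qc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(sf$samples, "results/discovery/samples_qc.csv", row.names = FALSE)
jsonlite::write_json(list(probes = pf$report, samples = sf$report),
                     "results/discovery/qc_report.json", auto_unbox = TRUE)

cat(sprintf("probes: %d -> %d (removed: %s)\n",
            pf$report$n_input, pf$report$n_retained,
            paste(names(pf$report$probes_removed),
                  pf$report$probes_removed, sep = "=", collapse = ", ")))
cat(sprintf("samples: %d -> %d (removed: %s)\n",
            sf$report$n_input, sf$report$n_retained,
            paste(names(sf$report$samples_removed),
                  sf$report$samples_removed, sep = "=", collapse = ", ")))
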