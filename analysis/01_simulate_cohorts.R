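#!/usr/bin/env Rscript
# Stage 1 — simulate the two study cohorts and the gene-set collection.
#
# The discovery cohort mimics a cord-blood methylation study with a
# zero-inflated continuous cotinine exposure (most mothers undetectable); the
# replication cohort carries the three-category smoking report encoded as an
# ordinal dose. Six genes receive an exposure-proportional methylation shift
# of 5e-4 per cotinine unit (~0.1 beta at the mean detected level), shared by
# both cohorts on their respective exposure scales. A handful of QC defects
# (failed samples, a sex mismatch, control/sex-chromosome probes, missing
# cells) are injected so the QC stage has real work to do.

suppressPackageStartupMessages(library(methscore))

seed <- 20160101L
out <- "results/data"
effect_disc <- setNames(rep(5e-4, 6), gene_ids(120)[1:6])
effect_repl <- setNames(rep(5e-2, 6), gene_ids(120)[1:6])  # per dose step

discovery <- generate_cohort(sim_config(
  n_samples = 600, n_genes = 120, cpgs_per_gene = c(2, 6),
  within_gene_correlation = 0.3,
  exposure_model = exposure_zero_inflated(),      # cotinine scale
  n_candidate_covariates = 6,
  effect_genes = effect_disc, missing_rate = 0.01, seed = seed))

replication <- generate_cohort(sim_config(
  n_samples = 400, n_genes = 120, cpgs_per_gene = c(2, 6),
  within_gene_correlation = 0.3,
  exposure_model = exposure_categorical3(),
  n_candidate_covariates = 6,
  effect_genes = effect_repl, seed = seed + 1))

# inject QC defects into the discovery cohort
set.seed(seed + 2)
discovery$samples$illumina_failed[c(5, 250)] <- TRUE
discovery$samples$sex_predicted[42] <-
  setdiff(c("F", "M"), discovery$samples$sex_reported[42])
discovery$samples$mean_detection_p[77] <- 0.30
discovery$annotation$is_control[1:3] <- TRUE
discovery$annotation$chromosome[10:13] <- "X"
discovery$annotation$chromosome[20:21] <- "Y"
bad_cpg <- sample(ncol(discovery$methylation), 4)
discovery$methylation[sample(600, 120), bad_cpg] <- NA  # ~20% missing

sets <- generate_gene_sets(40, c(4, 15), overlap = 0.15,
                           genes = gene_ids(120), seed = seed + 3,
                           include_filter_violations = TRUE)
# one curated set carrying the implanted genes
sets$sets$SET_001 <- names(effect_disc)

write_cohort(discovery, file.path(out, "discovery"))
write_cohort(replication, file.path(out, "replication"))
write_gmt(sets, file.path(out, "gene_sets.gmt"))
jsonlite::write_json(list(seed = seed,
                          effect_genes_discovery = as.list(effect_disc),
                          effect_genes_replication = as.list(effect_repl),
                          implanted_set = "SET_001"),
                     file.path(out, "simulation.json"), auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("discovery: %d samples x %d CpGs; replication: %d x %d; %d gene sets\n",
            nrow(discovery$methylation), ncol(discovery$methylation),
            nrow(replication$methylation), ncol(replication$methylation),
            length(sets)))
cat("implanted:", paste(names(effect_disc), collapse = ", "),
    "-> set SET_001\n")
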