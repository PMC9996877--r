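#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic pan-cancer-style cohort.
#
# Emulates the structure the CRS analysis assumes: a log2 expression
# matrix in which core-clock genes are up-shifted and clock-control
# genes down-shifted in tumors, overall survival linked to the true
# (noise-free) control-minus-core score through a proportional-hazards
# model, and uniform censoring. Everything downstream reads the TSV/GMT
# files written here.

library(crscore)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- cohort_params(seed = 1L)   # study defaults; see vignette
cohort <- simulate_cohort(params)

write_expression(cohort$expr, file.path(out, "expression_log2.tsv"))
write_clinical(cohort$clinical, file.path(out, "clinical.tsv"))
write_gmt(list(clock_control = cohort$pair$control,
               core_clock = cohort$pair$core),
          file.path(out, "crg_sets.gmt"))
write.table(data.frame(sample_id = names(cohort$tissue),
                       tissue = cohort$tissue,
                       true_score = cohort$true_score),
            file.path(out, "sample_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ev <- mean(cohort$clinical$os_event)
cat(sprintf("cohort: %d genes x %d samples (%d tumor / %d normal)\n",
            nrow(cohort$expr), ncol(cohort$expr),
            params$n_tumor, params$n_normal))
cat(sprintf("survival: %.0f%% events (censor target %.0f%%), median OS %.0f days\n",
            100 * ev, 100 * params$censor_rate,
            median(cohort$clinical$os_time_days)))
cat("wrote", out, "\n")
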