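#!/usr/bin/env Rscript
# Stage 4 — differential expression and SNV/CNV summaries.
#
# Tumor-vs-normal DEG calls on the circadian genes (Welch t on log2,
# fold-change > 2 and p < 0.05 gates), mutation frequency per gene,
# CNV categorization at +-0.3 and the CNV-expression coupling screen.

library(crscore)

expr <- read_expression("results/synthetic/expression_log2.tsv", unit = "log2")
ann <- read.delim("results/synthetic/sample_annotation.tsv")
tissue <- ann$tissue[match(colnames(expr), ann$sample_id)]
tumor <- expression_matrix(unclass(expr)[, tissue == "tumor"], unit = "log2")
normal <- expression_matrix(unclass(expr)[, tissue == "normal"], unit = "log2")

deg <- deg_call(tumor, normal)
gmt <- read_gmt("results/synthetic/crg_sets.gmt")
crg <- deg[deg$gene_id %in% unlist(gmt), ]
write.table(deg, "results/deg_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("DEGs among the %d circadian genes: %d up, %d down\n",
            nrow(crg), sum(crg$call == "up"), sum(crg$call == "down")))
cat(sprintf("  core-clock up: %d/%d; clock-control down: %d/%d\n",
            sum(crg$call == "up" & crg$gene_id %in% gmt$core_clock),
            length(gmt$core_clock),
            sum(crg$call == "down" & crg$gene_id %in% gmt$clock_control),
            length(gmt$clock_control)))

gen <- simulate_genomics(n_genes = 48L, n_samples = 200L, coupling = 0.8,
                         cnv_event_rate = 0.3, seed = 1L)
mf <- mutation_frequency(gen$mutations)
cat(sprintf("mutation burden: %.1f%% of samples carry >= 1 mutation\n",
            100 * mf$overall_mutated_fraction))
cat(sprintf("dominant class: %s (%d events)\n",
            names(which.max(mf$class_counts)), max(mf$class_counts)))
write.table(mf$frequency, "results/mutation_frequency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cnv <- cnv_categorize(gen$cnv)
cc <- cnv_expression_correlation(gen$cnv, gen$expr)
write.table(merge(cnv$frequency, cc, by = "gene_id"),
            "results/cnv_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("CNV: mean amp freq %.3f, del freq %.3f; CNV-mRNA rho: %d/%d genes with q < 0.05\n",
            mean(cnv$frequency$amp_freq), mean(cnv$frequency$del_freq),
            sum(cc$q < 0.05, na.rm = TRUE), nrow(cc)))
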