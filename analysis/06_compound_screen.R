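#!/usr/bin/env Rscript
# Stage 6 — connectivity-map compound screen.
#
# Builds the CRS query signature (top/bottom CRS-correlated genes),
# scores a simulated compound library with the bidirectional KS
# statistic per synthetic cancer type, scales to [-100, 100] and screens
# for compounds consistent in >= 10 of 18 cancers. One mimic and one
# revert compound are planted; the screen should recover exactly those.

library(crscore)

expr <- read_expression("results/synthetic/expression_log2.tsv", unit = "log2")
crs <- read.delim("results/crs.tsv")
scores <- setNames(crs$crs, crs$sample_id)

sig <- crs_gene_signature(expr, scores, n_top = 150L)
cat(sprintf("query signature: %d up / %d down genes (top |rho| = %.2f)\n",
            length(sig$up), length(sig$down), max(abs(sig$rho))))

n_cancers <- 18L
ids <- c(sprintf("CP%04d", 1:200), "MIMIC01", "REVERT01")
conn <- matrix(NA_real_, nrow = length(ids), ncol = n_cancers,
               dimnames = list(ids, sprintf("cancer%02d", 1:n_cancers)))
for (ca in seq_len(n_cancers)) {
  lib <- simulate_compound_library(n_compounds = 200L,
                                   universe = rownames(expr),
                                   query = sig,
                                   planted = c(MIMIC01 = "mimic",
                                               REVERT01 = "revert"),
                                   seed = 100L + ca)
  conn[names(lib), ca] <- score_library(sig, lib, scale = TRUE)
}
write_matrix_tsv(conn, "results/connectivity_matrix.tsv",
                 id_col = "compound_id")

hits <- compound_screen(conn, thresh = 90, min_cancers = 10L)
cat(sprintf("hits at |score| > 90 in >= 10/%d cancers: positive {%s}, negative {%s}\n",
            n_cancers, paste(hits$positive, collapse = ", "),
            paste(hits$negative, collapse = ", ")))
cat(sprintf("decoy score spread: median %.1f, max |score| %.1f\n",
            median(conn[1:200, ]), max(abs(conn[1:200, ]))))
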