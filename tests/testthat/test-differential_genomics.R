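test_that("FPKM to TPM renormalizes columns to one million", {
  e <- expression_matrix(matrix(c(1, 3), ncol = 1,
                                dimnames = list(c("a", "b"), "s")),
                         unit = "FPKM")
  tpm <- fpkm_to_tpm(e)
  expect_equal(unname(unclass(tpm)[, 1]), c(250000, 750000))
  expect_identical(attr(tpm, "unit"), "TPM")
  # scale invariance per column
  e2 <- expression_matrix(unclass(e) * 7, unit = "FPKM")
  expect_equal(unclass(fpkm_to_tpm(e2)), unclass(tpm), tolerance = 1e-12)
  # already at 1e6 stays put
  e3 <- expression_matrix(matrix(c(4e5, 6e5), ncol = 1,
                                 dimnames = list(c("a", "b"), "s")),
                          unit = "FPKM")
  expect_equal(as.vector(fpkm_to_tpm(e3)), as.vector(unclass(e3)),
               tolerance = 1e-12)
  z <- expression_matrix(matrix(0, ncol = 1, nrow = 2,
                                dimnames = list(c("a", "b"), "s")),
                         unit = "FPKM")
  expect_error(fpkm_to_tpm(z), "zero column sum")
  expect_error(fpkm_to_tpm(tpm), "unit must be FPKM")
})

make_groups <- function(shift_gene, shift, n = 20, sd = 0.5, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:10)
  tum <- matrix(rnorm(10 * n, 5, sd), nrow = 10,
                dimnames = list(genes, sprintf("t%02d", 1:n)))
  nor <- matrix(rnorm(10 * n, 5, sd), nrow = 10,
                dimnames = list(genes, sprintf("n%02d", 1:n)))
  tum[shift_gene, ] <- tum[shift_gene, ] + shift
  list(t = expression_matrix(tum, unit = "log2"),
       n = expression_matrix(nor, unit = "log2"))
}

test_that("DEG calls obey both the fold-change and the p gates", {
  g <- make_groups("g01", shift = 2)
  deg <- deg_call(g$t, g$n)
  expect_identical(deg$call[deg$gene_id == "g01"], "up")
  # a clear shift below the fold-change gate stays ns at any p
  g2 <- make_groups("g01", shift = log2(1.5), n = 200, sd = 0.1)
  deg2 <- deg_call(g2$t, g2$n)
  rec <- deg2[deg2$gene_id == "g01", ]
  expect_lt(rec$p, 0.001)
  expect_identical(rec$call, "ns")
  # identical matrices: all ns, all zero fold changes
  deg3 <- deg_call(g$t, g$t)
  expect_true(all(deg3$call == "ns"))
  expect_true(all(deg3$log2_fc == 0))
})

test_that("DEG calling is symmetric under swapping tumor and normal", {
  g <- make_groups("g03", shift = -2.5, seed = 4)
  a <- deg_call(g$t, g$n)
  b <- deg_call(g$n, g$t)
  expect_equal(a$log2_fc, -b$log2_fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_identical(a$call == "up", b$call == "down")
  bad <- expression_matrix(unclass(g$n)[1:5, , drop = FALSE], unit = "log2")
  expect_error(deg_call(g$t, bad), "universes differ")
})

test_that("planted two-fold shift is called up with high power", {
  hits <- vapply(1:30, function(s) {
    g <- make_groups("g05", shift = 2, n = 20, sd = 0.5, seed = 100 + s)
    deg_call(g$t, g$n)$call[5] == "up"
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("mutation frequency follows the printed formula and collapses multi-hits", {
  mut <- data.frame(
    sample_id = c("s1", "s2", "s1", "s1"),
    gene_id = c("PER3", "PER3", "TIM", "TIM"),
    variant_class = c("missense", "nonsense", "missense", "splice_site"),
    cohort = "all", stringsAsFactors = FALSE)
  res <- mutation_frequency(mutation_table(mut, cohort_sizes = c(all = 50L)))
  f <- res$frequency
  expect_equal(f$freq[f$gene_id == "PER3"], 2 / 50)
  expect_equal(f$freq[f$gene_id == "TIM"], 1 / 50)
  expect_equal(unname(res$class_counts["multi_hit"]), 1L)
  # invariance to row order and duplicated rows
  perm <- mut[c(4, 1, 3, 2, 1), ]
  res2 <- mutation_frequency(mutation_table(perm, cohort_sizes = c(all = 50L)))
  expect_equal(res2$frequency[order(res2$frequency$gene_id), ],
               f[order(f$gene_id), ], ignore_attr = TRUE)
  expect_error(
    mutation_table(mut, cohort_sizes = c(all = 1L)),
    "more mutated samples")
  empty <- mutation_frequency(
    mutation_table(mut[0, ], cohort_sizes = c(all = 10L)))
  expect_equal(nrow(empty$frequency), 0L)
  expect_equal(empty$overall_mutated_fraction, 0)
})

test_that("CNV categorization thresholds and symmetry behave as documented", {
  m <- matrix(c(0.31, -0.31, 0, 0.3, -0.3, 1.2), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  cat <- cnv_categorize(m)$categorized
  expect_identical(as.vector(cat), c(1L, -1L, 0L, 0L, 0L, 1L))
  z <- cnv_categorize(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_true(all(z$frequency$amp_freq == 0) && all(z$frequency$del_freq == 0))
  # negation swaps amplification and deletion frequencies exactly
  set.seed(6)
  r <- matrix(rnorm(200), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:20)))
  a <- cnv_categorize(r)
  b <- cnv_categorize(-r)
  expect_equal(a$frequency$amp_freq, b$frequency$del_freq)
  expect_equal(a$categorized, -b$categorized)
  expect_error(cnv_categorize(r, lo = 0.3, hi = 0.3), "lo must be <")
})

test_that("CNV-expression correlation handles monotone and constant genes", {
  cnv <- matrix(seq(-1, 1, length.out = 20), nrow = 2, ncol = 20, byrow = TRUE,
                dimnames = list(c("mono", "flat"), sprintf("s%02d", 1:20)))
  cnv["flat", ] <- 0
  set.seed(3)
  exm <- rbind(mono = exp(cnv["mono", ]), flat = rnorm(20))
  colnames(exm) <- colnames(cnv)
  ex <- expression_matrix(exm, unit = "log2")
  out <- cnv_expression_correlation(cnv, ex)
  expect_equal(out$rho[out$gene_id == "mono"], 1)
  expect_true(is.na(out$rho[out$gene_id == "flat"]))
  expect_error(cnv_expression_correlation(cnv[, 1:3], ex[, 1:3]),
               ">= 5 shared samples")
})
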