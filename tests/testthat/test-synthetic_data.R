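test_that("identical params and seed give byte-identical cohorts", {
  p <- cohort_params(n_genes_background = 100L, n_tumor = 20L, n_normal = 10L,
                     seed = 42L)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  c2 <- simulate_cohort(cohort_params(n_genes_background = 100L,
                                      n_tumor = 20L, n_normal = 10L,
                                      seed = 43L))
  expect_false(identical(unclass(a$expr), unclass(c2$expr)))
})

test_that("cohort outputs satisfy their type invariants", {
  co <- simulate_cohort(cohort_params(n_genes_background = 150L, seed = 9L))
  expect_s3_class(co$expr, "expr_matrix")
  expect_false(anyNA(unclass(co$expr)))
  expect_true(all(co$clinical$os_time_days > 0))
  expect_true(all(co$clinical$os_event %in% 0:1))
  expect_equal(sort(unique(co$tissue)), c("normal", "tumor"))
  expect_equal(mean(co$true_score[co$tissue == "tumor"]), 0, tolerance = 1e-10)
  expect_equal(sd(co$true_score[co$tissue == "tumor"]), 1, tolerance = 1e-10)
  expect_error(cohort_params(censor_rate = 1), "censor_rate")
  expect_error(cohort_params(n_normal = 1), ">= 2")
})

test_that("null effects make tumor and normal CRS indistinguishable", {
  ps <- vapply(1:15, function(s) {
    co <- simulate_cohort(cohort_params(n_genes_background = 100L,
                                        n_tumor = 30L, n_normal = 30L,
                                        effect_core_log2 = 0,
                                        effect_control_log2 = 0, seed = s))
    crs <- compute_crs(co$expr, co$pair, alpha = 0.25)
    compare_crs_groups(crs$crs, co$tissue, test = "wilcoxon")$p
  }, numeric(1))
  # p roughly uniform: no mass collapse near 0
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("null hazard gives nominal log-rank size at the median split", {
  rej <- vapply(1:60, function(s) {
    co <- simulate_cohort(cohort_params(n_genes_background = 30L,
                                        n_tumor = 60L, n_normal = 2L,
                                        hazard_beta = 0, seed = 7000L + s))
    g <- ifelse(co$true_score[co$clinical$sample_id] >
                  median(co$true_score[co$clinical$sample_id]), "hi", "lo")
    logrank_test(co$clinical$os_time_days, co$clinical$os_event, g)$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.18)  # ~5% nominal, allow Monte-Carlo slack at n=60
})

test_that("knockout generator respects its contract", {
  base <- cohort_params(n_genes_background = 80L, seed = 3L)
  ko <- simulate_knockout(knockdown_factor = 0, base = base)
  expect_true(all(unclass(ko$expr)[ko$target_genes, ko$group == "ko"] == 0))
  ident <- simulate_knockout(knockdown_factor = 1, base = base)
  # factor 1: KO and control columns come from the same generative law
  expect_equal(dim(ident$expr), dim(ko$expr))
  expect_true(all(unclass(ident$expr) > 0))
  expect_error(simulate_knockout(knockdown_factor = 2, base = base),
               "knockdown_factor")
})

test_that("genomics generator couples CNV and expression as requested", {
  g0 <- simulate_genomics(n_genes = 40L, n_samples = 500L, coupling = 0,
                          seed = 21L)
  rho0 <- cnv_expression_correlation(g0$cnv, g0$expr)
  expect_lt(mean(abs(rho0$rho), na.rm = TRUE), 0.05)
  # strong coupling: genes with a dense event load correlate strongly
  # (samples without an event contribute only noise to the rank
  # correlation, so the event rate bounds the attainable rho)
  g1 <- simulate_genomics(n_genes = 40L, n_samples = 500L, coupling = 3,
                          cnv_event_rate = 0.5, seed = 22L)
  rho1 <- cnv_expression_correlation(g1$cnv, g1$expr)
  cat1 <- cnv_categorize(g1$cnv)$categorized
  busy <- rowSums(cat1 != 0) >= 10
  expect_true(all(rho1$rho[match(rownames(cat1)[busy], rho1$gene_id)] > 0.5))
  empty <- simulate_genomics(n_genes = 10L, n_samples = 20L,
                             per_gene_mut_rate = 0, seed = 1L)
  expect_equal(nrow(empty$mutations), 0L)
})

test_that("compound library plants mimics at the top and reverts at the bottom", {
  universe <- sprintf("g%04d", 1:500)
  q <- list(up = universe[1:20], down = universe[481:500])
  lib <- simulate_compound_library(n_compounds = 50L, universe = universe,
                                   query = q,
                                   planted = c(M1 = "mimic", R1 = "revert"),
                                   seed = 31L)
  raw <- score_library(q, lib, scale = FALSE)
  expect_equal(names(which.max(raw)), "M1")
  expect_equal(names(which.min(raw)), "R1")
  scaled <- scale_scores(raw)
  decoys <- setdiff(names(scaled), c("M1", "R1"))
  expect_lt(abs(median(scaled[decoys])), 20)
})

test_that("fraction columns are Dirichlet-normalized and track the linked score", {
  link <- c(0.8, rep(0, 21L))
  fr <- simulate_fractions(n_samples = 300L, crs_link = link, seed = 41L)
  expect_equal(unname(colSums(fr$fractions)), rep(1, 300), tolerance = 1e-12)
  rec <- fraction_crs_correlation(fr$fractions, fr$score)
  linked <- rec[rec$feature_id == "CellType01", ]
  expect_gt(linked$rho, 0)
  expect_lt(linked$q, 0.05)
  null_rho <- rec$rho[rec$feature_id != "CellType01"]
  expect_lt(abs(mean(null_rho)), 0.12)
})
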