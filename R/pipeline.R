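# End-to-end orchestration: simulate -> score -> stratify -> survival /
# genomics / immune / connectivity, with a validated config and a
# manifest of content-hashed outputs.

#' Default pipeline configuration
#'
#' All tunable pipeline parameters in one documented list; any subset can
#' be overridden via [run_pipeline()]'s `config` (R list or YAML file).
#'
#' @return named list of defaults: ssGSEA `alpha` (0.25) and `normalize`;
#'   CRS `sign_convention`; cutpoint `minprop` (0.1); DEG thresholds
#'   (`fc_thresh` 2, `p_thresh` 0.05); CNV thresholds (+-0.3); ICG screen
#'   thresholds (`icg_r_thresh` 0.7, `icg_p_thresh` 0.05); compound screen
#'   (`conn_thresh` 90, `conn_min_cancers` 10, `n_top` 150); `seed`; the
#'   simulated cohort's [cohort_params()] fields under `cohort`.
#' @export
default_config <- function() {
  list(alpha = 0.25, normalize = FALSE,
       sign_convention = "control_minus_core",
       minprop = 0.1,
       fc_thresh = 2, p_thresh = 0.05,
       cnv_lo = -0.3, cnv_hi = 0.3,
       icg_r_thresh = 0.7, icg_p_thresh = 0.05,
       conn_thresh = 90, conn_min_cancers = 10, n_top = 150,
       seed = 1L,
       cohort = list())
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$seed)) stop("config: seed is mandatory")
  if (cfg$alpha < 0) stop("config: alpha must be >= 0")
  if (cfg$minprop <= 0 || cfg$minprop >= 0.5)
    stop("config: minprop must be in (0, 0.5)")
  if (cfg$fc_thresh <= 1) stop("config: fc_thresh must be > 1")
  if (cfg$p_thresh <= 0 || cfg$p_thresh >= 1)
    stop("config: p_thresh must be in (0, 1)")
  if (cfg$cnv_lo >= cfg$cnv_hi) stop("config: cnv_lo must be < cnv_hi")
  if (cfg$icg_r_thresh <= 0 || cfg$icg_r_thresh >= 1)
    stop("config: icg_r_thresh must be in (0, 1)")
  if (cfg$conn_thresh <= 0 || cfg$conn_thresh > 100)
    stop("config: conn_thresh must be in (0, 100]")
  if (!cfg$sign_convention %in% c("control_minus_core", "core_minus_control"))
    stop("config: unknown sign_convention")
  cfg
}

#' Run the synthetic end-to-end CRS pipeline
#'
#' Stages, in dependency order: simulate a tumor/normal cohort with
#' survival; compute per-sample CRS; stratify tumors at the optimal
#' cutpoint and run Kaplan-Meier / log-rank / univariate Cox; simulate
#' and summarize genomics (mutation frequency, CNV categories,
#' CNV-expression correlation); simulate fractions linked to the CRS and
#' run the immune screens; build the CRS signature and screen a
#' simulated compound library. All outputs are written as TSV under
#' `out_dir` and recorded in a manifest with md5 content hashes; a rerun
#' with the identical config reproduces identical hashes.
#'
#' @param config named list overriding [default_config()], or the path of
#'   a YAML file of such overrides.
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly also written to
#'   `<out_dir>/manifest.json`): parameters, per-stage output files with
#'   hashes, headline statistics, warnings.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("crscore_run_")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  outputs <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  # stage 1: cohort
  cp <- do.call(cohort_params, utils::modifyList(list(seed = cfg$seed),
                                                 cfg$cohort))
  cohort <- simulate_cohort(cp)
  log_stage("simulate", sprintf("%d genes x %d samples, %d tumor",
                                nrow(cohort$expr), ncol(cohort$expr),
                                cp$n_tumor))
  emit("expression.tsv", function(p) write_expression(cohort$expr, p))
  emit("clinical.tsv", function(p) write_clinical(cohort$clinical, p))
  emit("crg_sets.gmt", function(p)
    write_gmt(list(clock_control = cohort$pair$control,
                   core_clock = cohort$pair$core), p))

  # stage 2: CRS
  crs <- compute_crs(cohort$expr, cohort$pair, alpha = cfg$alpha,
                     normalize = cfg$normalize,
                     sign_convention = cfg$sign_convention,
                     tissue = cohort$tissue)
  tn <- compare_crs_groups(crs$crs, crs$tissue, test = "t")
  log_stage("crs", sprintf("tumor-vs-normal t-test p = %.3g", tn$p))

  # stage 3: stratify + survival
  tum <- crs[crs$tissue == "tumor", ]
  cl <- cohort$clinical[match(tum$sample_id, cohort$clinical$sample_id), ]
  cut <- optimal_cutpoint(tum$crs, cl$os_time_days, cl$os_event,
                          minprop = cfg$minprop)
  tum$group <- stratify_at_cutpoint(tum$crs, cut$cutpoint)
  crs$group[match(tum$sample_id, crs$sample_id)] <- tum$group
  lr <- logrank_test(cl$os_time_days, cl$os_event, tum$group)
  cox <- cox_univariate(tum$crs, cl$os_time_days, cl$os_event)
  km_high <- km_curve(cl$os_time_days[tum$group == "high"],
                      cl$os_event[tum$group == "high"])
  km_low <- km_curve(cl$os_time_days[tum$group == "low"],
                     cl$os_event[tum$group == "low"])
  log_stage("survival", sprintf(
    "cutpoint %.3f, log-rank p = %.3g (selection-biased), Cox HR = %.2f",
    cut$cutpoint, lr$p, cox$hr))
  emit("crs.tsv", function(p)
    utils::write.table(crs, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("km_curves.tsv", function(p) {
    km_high$group <- "high"; km_low$group <- "low"
    utils::write.table(rbind(km_high, km_low), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # stage 4: genomics
  gen <- simulate_genomics(n_genes = 48L, n_samples = cp$n_tumor,
                           seed = cfg$seed)
  mf <- mutation_frequency(gen$mutations)
  cnv <- cnv_categorize(gen$cnv, lo = cfg$cnv_lo, hi = cfg$cnv_hi)
  cnv_cor <- cnv_expression_correlation(gen$cnv, gen$expr)
  log_stage("genomics", sprintf(
    "%.1f%% of samples mutated; mean |CNV-expr rho| = %.2f",
    100 * mf$overall_mutated_fraction, mean(abs(cnv_cor$rho), na.rm = TRUE)))
  emit("mutation_frequency.tsv", function(p)
    utils::write.table(mf$frequency, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("cnv_frequency.tsv", function(p)
    utils::write.table(cnv$frequency, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("cnv_expression_correlation.tsv", function(p)
    utils::write.table(cnv_cor, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  # stage 5: immune
  link <- c(0.6, -0.6, rep(0, 20L))
  fr <- simulate_fractions(n_samples = nrow(tum),
                           crs_link = link,
                           score = stats::setNames(scale(tum$crs)[, 1L],
                                                   tum$sample_id),
                           seed = cfg$seed)
  colnames(fr$fractions) <- tum$sample_id
  grp <- stats::setNames(tum$group, tum$sample_id)
  fg <- fraction_group_test(fr$fractions, grp)
  fc <- fraction_crs_correlation(fr$fractions,
                                 stats::setNames(tum$crs, tum$sample_id))
  log_stage("immune", sprintf("%d/%d cell types differ between CRS groups",
                              sum(fg$significant), nrow(fg)))
  emit("fraction_group_test.tsv", function(p)
    utils::write.table(fg, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("fraction_crs_correlation.tsv", function(p)
    utils::write.table(fc, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # stage 6: connectivity
  sig <- crs_gene_signature(cohort$expr, stats::setNames(crs$crs, crs$sample_id),
                            n_top = min(cfg$n_top, nrow(cohort$expr) %/% 2L))
  lib <- simulate_compound_library(n_compounds = 50L,
                                   universe = rownames(cohort$expr),
                                   query = sig,
                                   planted = c(MIMIC01 = "mimic",
                                               REVERT01 = "revert"),
                                   seed = cfg$seed)
  scores <- score_library(sig, lib)
  log_stage("connectivity", sprintf("planted mimic score %.0f, revert %.0f",
                                    scores["MIMIC01"], scores["REVERT01"]))
  emit("connectivity_scores.tsv", function(p)
    utils::write.table(data.frame(compound_id = names(scores),
                                  score = unname(scores)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("crscore")),
    parameters = cfg,
    outputs = outputs,
    statistics = list(
      tumor_normal_p = tn$p,
      cutpoint = cut$cutpoint,
      logrank_p = lr$p,
      logrank_selection_biased = TRUE,
      cox_beta = cox$beta, cox_hr = cox$hr, cox_p = cox$p,
      overall_mutated_fraction = mf$overall_mutated_fraction,
      n_significant_celltypes = sum(fg$significant),
      mimic_score = unname(scores["MIMIC01"]),
      revert_score = unname(scores["REVERT01"])
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
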