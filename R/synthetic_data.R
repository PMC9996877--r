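# Synthetic cohorts with the statistical structure the CRS analysis
# assumes: tumor/normal contrasts on the two circadian gene classes,
# CRS-linked proportional-hazards survival, knockout cohorts, 24-h time
# courses, genomics (SNV/CNV/expression coupling), compound libraries
# and immune-fraction matrices.
#
# Each generator draws from per-stage derived seeds (master seed + fixed
# offsets), so adding a downstream draw never perturbs earlier ones and
# identical params + seed give byte-identical output.

.stream_seed <- function(seed, stream) {
  offsets <- c(mu = 1L, noise = 11L, survival = 21L, censor = 31L,
               phase = 41L, mutation = 51L, cnv = 61L, coupling = 71L,
               library = 81L, fractions = 91L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

#' Parameters of a synthetic tumor/normal cohort
#'
#' Defaults encode the study conditions the analysis assumes: 13
#' clock-control and 35 core-clock genes over a 1000-gene background,
#' core genes shifted up (+1 log2) and control genes down (-1 log2) in
#' tumors, residual log2 noise sd 0.5, survival from an exponential
#' proportional-hazards model on the true (noise-free) score with
#' independent uniform censoring.
#'
#' @param n_genes_background background (non-circadian) gene count.
#' @param control_set_size,core_set_size circadian class sizes.
#' @param n_tumor,n_normal sample counts (>= 2 each).
#' @param effect_core_log2 mean tumor up-shift of core genes (log2).
#' @param effect_control_log2 mean tumor shift of control genes (log2).
#' @param noise_sd_log2 residual per-cell noise sd (log2 units).
#' @param hazard_beta log-hazard per unit of standardized true score.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censor_rate expected fraction of censored tumor samples, in [0, 1).
#' @param seed master RNG seed.
#' @return validated parameter list of class `cohort_params`.
#' @export
cohort_params <- function(n_genes_background = 1000L, control_set_size = 13L,
                          core_set_size = 35L, n_tumor = 100L, n_normal = 50L,
                          effect_core_log2 = 1.0, effect_control_log2 = -1.0,
                          noise_sd_log2 = 0.5, hazard_beta = 0.8,
                          baseline_hazard = 0.002, censor_rate = 0.3,
                          seed = 1L) {
  p <- list(n_genes_background = as.integer(n_genes_background),
            control_set_size = as.integer(control_set_size),
            core_set_size = as.integer(core_set_size),
            n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
            effect_core_log2 = effect_core_log2,
            effect_control_log2 = effect_control_log2,
            noise_sd_log2 = noise_sd_log2, hazard_beta = hazard_beta,
            baseline_hazard = baseline_hazard, censor_rate = censor_rate,
            seed = as.integer(seed))
  if (p$control_set_size < 1L || p$core_set_size < 1L)
    stop("set sizes must be >= 1")
  if (p$n_tumor < 2L || p$n_normal < 2L)
    stop("n_tumor and n_normal must be >= 2")
  if (p$censor_rate < 0 || p$censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (p$noise_sd_log2 <= 0) stop("noise_sd_log2 must be > 0")
  if (p$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  structure(p, class = "cohort_params")
}

.cohort_genes <- function(p) {
  list(background = sprintf("BG%04d", seq_len(p$n_genes_background)),
       control = sprintf("CTL%02d", seq_len(p$control_set_size)),
       core = sprintf("CORE%02d", seq_len(p$core_set_size)))
}

# baseline log2 abundance per gene, drawn once per seed
.cohort_mu <- function(p, genes) {
  set.seed(.stream_seed(p$seed, "mu"))
  stats::setNames(stats::rnorm(length(genes), mean = 6, sd = 2), genes)
}

#' Simulate a tumor/normal cohort with CRS-linked survival
#'
#' Background genes are Normal(mu_g, noise_sd) on the log2 scale with
#' gene-level means drawn once; in tumor samples only, core-clock genes
#' shift by `effect_core_log2` and clock-control genes by
#' `effect_control_log2`. The true score is the per-sample
#' (mean control - mean core) expression, standardized over tumor
#' samples; tumor survival times are exponential with rate
#' `baseline_hazard * exp(hazard_beta * true_score)` under independent
#' uniform censoring calibrated to `censor_rate`.
#'
#' @param params a [cohort_params()].
#' @return list: `expr` (log2 [expression_matrix()]), `clinical` (tumor
#'   samples: `sample_id`, `os_time_days`, `os_event`), `pair`
#'   ([gene_set_pair()]), `tissue` (named tumor/normal labels),
#'   `true_score` (named, standardized), `params`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  p <- params
  g <- .cohort_genes(p)
  genes <- c(g$background, g$control, g$core)
  samples <- c(sprintf("T%03d", seq_len(p$n_tumor)),
               sprintf("N%03d", seq_len(p$n_normal)))
  is_tumor <- c(rep(TRUE, p$n_tumor), rep(FALSE, p$n_normal))
  mu <- .cohort_mu(p, genes)
  set.seed(.stream_seed(p$seed, "noise"))
  expr <- matrix(stats::rnorm(length(genes) * length(samples), sd = p$noise_sd_log2),
                 nrow = length(genes), dimnames = list(genes, samples)) + mu
  expr[g$core, is_tumor] <- expr[g$core, is_tumor] + p$effect_core_log2
  expr[g$control, is_tumor] <- expr[g$control, is_tumor] + p$effect_control_log2
  raw_score <- colMeans(expr[g$control, , drop = FALSE]) -
    colMeans(expr[g$core, , drop = FALSE])
  mu_t <- mean(raw_score[is_tumor])
  sd_t <- stats::sd(raw_score[is_tumor])
  true_score <- (raw_score - mu_t) / sd_t
  lambda <- p$baseline_hazard * exp(p$hazard_beta * true_score[is_tumor])
  set.seed(.stream_seed(p$seed, "survival"))
  t_event <- stats::rexp(p$n_tumor, rate = lambda)
  set.seed(.stream_seed(p$seed, "censor"))
  if (p$censor_rate > 0) {
    tau <- .censor_tau(lambda, p$censor_rate)
    c_time <- stats::runif(p$n_tumor, 0, tau)
    os_time <- pmin(t_event, c_time)
    os_event <- as.integer(t_event <= c_time)
  } else {
    os_time <- t_event
    os_event <- rep(1L, p$n_tumor)
  }
  clinical <- data.frame(sample_id = samples[is_tumor],
                         os_time_days = os_time, os_event = os_event,
                         stringsAsFactors = FALSE)
  list(expr = expression_matrix(expr, unit = "log2"),
       clinical = clinical,
       pair = gene_set_pair(control = g$control, core = g$core),
       tissue = stats::setNames(ifelse(is_tumor, "tumor", "normal"), samples),
       true_score = true_score,
       params = p)
}

# uniform-censoring horizon tau such that the expected censored fraction
# over the cohort's exponential hazards equals `rate`
.censor_tau <- function(lambda, rate) {
  f <- function(tau) mean((1 - exp(-lambda * tau)) / (lambda * tau)) - rate
  upper <- 1 / min(lambda)
  while (f(upper) > 0) upper <- upper * 4
  stats::uniroot(f, c(1e-9 / max(lambda), upper), tol = 1e-10)$root
}

#' Simulate a gene-knockout cohort
#'
#' Control and knockout samples share the cohort's background structure
#' (no tumor shifts); in knockout samples the target genes' linear-scale
#' expression is multiplied by `knockdown_factor` (0 = full knockout).
#'
#' @param target_genes gene ids to knock down; defaults to the cohort's
#'   core-clock set.
#' @param n_ko,n_ctrl sample counts.
#' @param knockdown_factor residual expression fraction in [0, 1].
#' @param base a [cohort_params()] providing gene structure, baseline
#'   means, noise and seed.
#' @return list: `expr` (linear-unit [expression_matrix()]), `group`
#'   (named ko/ctrl labels), `pair`, `target_genes`.
#' @export
simulate_knockout <- function(target_genes = NULL, n_ko = 10L, n_ctrl = 10L,
                              knockdown_factor = 0,
                              base = cohort_params()) {
  if (knockdown_factor < 0 || knockdown_factor > 1)
    stop("knockdown_factor must be in [0, 1]")
  g <- .cohort_genes(base)
  if (is.null(target_genes)) target_genes <- g$core
  genes <- c(g$background, g$control, g$core)
  if (!all(target_genes %in% genes)) stop("unknown target gene(s)")
  samples <- c(sprintf("KO%03d", seq_len(n_ko)),
               sprintf("CTRL%03d", seq_len(n_ctrl)))
  group <- stats::setNames(rep(c("ko", "ctrl"), c(n_ko, n_ctrl)), samples)
  mu <- .cohort_mu(base, genes)
  set.seed(.stream_seed(base$seed, "noise"))
  log2e <- matrix(stats::rnorm(length(genes) * length(samples),
                               sd = base$noise_sd_log2),
                  nrow = length(genes), dimnames = list(genes, samples)) + mu
  lin <- 2^log2e
  lin[target_genes, group == "ko"] <- lin[target_genes, group == "ko"] *
    knockdown_factor
  list(expr = expression_matrix(lin, unit = "FPKM"), group = group,
       pair = gene_set_pair(control = g$control, core = g$core),
       target_genes = target_genes)
}

#' Simulate a circadian time course with and without deregulation
#'
#' Circadian genes oscillate as `A * sin(2 pi t / period + phi_g)` around
#' their baseline; the normal group uses `amplitude_normal`, the
#' circadian-deregulation-treatment (CDT) group the smaller
#' `amplitude_cdt`. Clock-control genes get per-gene phases jittered
#' around 0 and core-clock genes around pi — the antiphase relation of
#' the stabilizing loop (REV-ERB/ROR, D-box factors) to the CLOCK:BMAL1
#' limb — so the control-minus-core score itself oscillates. Background
#' genes are non-rhythmic.
#'
#' @param timepoints_h sampling times in hours (>= 2 distinct).
#' @param period_h oscillation period (default 24 h).
#' @param amplitude_normal,amplitude_cdt log2 oscillation amplitudes,
#'   `amplitude_cdt < amplitude_normal`.
#' @param n_per_timepoint replicate samples per group and timepoint.
#' @param base a [cohort_params()] providing gene structure, noise, seed.
#' @return list: `expr` (log2), `annotation` (`sample_id`, `group`,
#'   `timepoint_h`), `pair`.
#' @export
simulate_timecourse <- function(timepoints_h = seq(0, 44, by = 4),
                                period_h = 24, amplitude_normal = 1,
                                amplitude_cdt = 0.25, n_per_timepoint = 3L,
                                base = cohort_params()) {
  if (length(unique(timepoints_h)) < 1L) stop("needs >= 1 timepoint")
  if (amplitude_cdt >= amplitude_normal)
    stop("amplitude_cdt must be < amplitude_normal")
  g <- .cohort_genes(base)
  genes <- c(g$background, g$control, g$core)
  crg <- c(g$control, g$core)
  mu <- .cohort_mu(base, genes)
  set.seed(.stream_seed(base$seed, "phase"))
  phi <- stats::setNames(
    c(stats::rnorm(length(g$control), mean = 0, sd = 0.3),
      stats::rnorm(length(g$core), mean = pi, sd = 0.3)), crg)
  ann <- expand.grid(rep = seq_len(n_per_timepoint),
                     timepoint_h = timepoints_h,
                     group = c("normal", "cdt"),
                     stringsAsFactors = FALSE)
  ann$sample_id <- sprintf("%s_t%02d_r%d",
                           ifelse(ann$group == "normal", "NRM", "CDT"),
                           match(ann$timepoint_h, sort(unique(timepoints_h))),
                           ann$rep)
  set.seed(.stream_seed(base$seed, "noise"))
  expr <- matrix(stats::rnorm(length(genes) * nrow(ann), sd = base$noise_sd_log2),
                 nrow = length(genes),
                 dimnames = list(genes, ann$sample_id)) + mu
  for (i in seq_len(nrow(ann))) {
    A <- if (ann$group[i] == "normal") amplitude_normal else amplitude_cdt
    expr[crg, i] <- expr[crg, i] +
      A * sin(2 * pi * ann$timepoint_h[i] / period_h + phi)
  }
  list(expr = expression_matrix(expr, unit = "log2"),
       annotation = ann[c("sample_id", "group", "timepoint_h")],
       pair = gene_set_pair(control = g$control, core = g$core))
}

#' Simulate coupled mutation, CNV and expression data
#'
#' Mutations are Bernoulli per gene x sample (class drawn from the eight
#' canonical variant classes, missense-weighted). CNV focal scores are a
#' mixture of 0-centered noise and, with probability `cnv_event_rate`,
#' signed events beyond |0.3|. Expression is shifted by
#' `coupling * categorized CNV`, realizing copy-number/expression
#' association.
#'
#' @param n_genes,n_samples dimensions.
#' @param per_gene_mut_rate Bernoulli mutation probability per gene x
#'   sample. The default 0.0101 makes ~38.6% of samples carry at least
#'   one mutation across a 48-gene panel, the burden typical of
#'   pan-cancer circadian-gene cohorts.
#' @param cnv_event_rate probability of an amplification/deletion event.
#' @param coupling log2 expression shift per CNV category unit.
#' @param seed master seed.
#' @return list: `mutations` (`mutation_table` with cohort "all"),
#'   `cnv` (gene x sample focal scores), `expr` (log2).
#' @export
simulate_genomics <- function(n_genes = 50L, n_samples = 100L,
                              per_gene_mut_rate = 0.0101, cnv_event_rate = 0.1,
                              coupling = 0.5, seed = 1L) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%04d", seq_len(n_samples))
  set.seed(.stream_seed(seed, "mutation"))
  hit <- matrix(stats::runif(n_genes * n_samples) < per_gene_mut_rate,
                nrow = n_genes, dimnames = list(genes, samples))
  idx <- which(hit, arr.ind = TRUE)
  classes <- sample(VARIANT_CLASSES, nrow(idx), replace = TRUE,
                    prob = c(0.55, 0.1, 0.05, 0.06, 0.08, 0.08, 0.04, 0.04))
  mut <- data.frame(sample_id = samples[idx[, 2L]], gene_id = genes[idx[, 1L]],
                    variant_class = classes,
                    cohort = rep("all", nrow(idx)),
                    stringsAsFactors = FALSE)
  mut <- mut[order(mut$sample_id, mut$gene_id), , drop = FALSE]
  rownames(mut) <- NULL
  set.seed(.stream_seed(seed, "cnv"))
  noise <- matrix(stats::rnorm(n_genes * n_samples, sd = 0.1),
                  nrow = n_genes, dimnames = list(genes, samples))
  is_event <- matrix(stats::runif(n_genes * n_samples) < cnv_event_rate,
                     nrow = n_genes)
  sign_e <- matrix(sample(c(-1, 1), n_genes * n_samples, replace = TRUE),
                   nrow = n_genes)
  magnitude <- matrix(0.35 + abs(stats::rnorm(n_genes * n_samples, sd = 0.3)),
                      nrow = n_genes)
  cnv <- noise
  cnv[is_event] <- (sign_e * magnitude)[is_event]
  set.seed(.stream_seed(seed, "coupling"))
  cat_cnv <- cnv_categorize(cnv)$categorized
  expr <- matrix(stats::rnorm(n_genes * n_samples, mean = 8, sd = 1),
                 nrow = n_genes, dimnames = list(genes, samples)) +
    coupling * cat_cnv
  list(mutations = mutation_table(mut,
         cohort_sizes = c(all = as.integer(n_samples))),
       cnv = cnv,
       expr = expression_matrix(expr, unit = "log2"))
}

#' Simulate a compound signature library with planted hits
#'
#' Unplanted compounds are independent random permutations of the
#' universe. A planted `"mimic"` compound ranks the query's up-genes at
#' the very top and its down-genes at the very bottom; a `"revert"`
#' compound does the opposite.
#'
#' @param n_compounds decoy (unplanted) compound count.
#' @param universe character gene universe common to all compounds.
#' @param query a `query_signature` (or list with `up`/`down`); required
#'   when `planted` is non-empty.
#' @param planted named character vector, compound id -> `"mimic"` or
#'   `"revert"`.
#' @param seed master seed.
#' @return a `signature_library`.
#' @export
simulate_compound_library <- function(n_compounds = 100L, universe,
                                      query = NULL, planted = NULL,
                                      seed = 1L) {
  set.seed(.stream_seed(seed, "library"))
  lib <- lapply(seq_len(n_compounds), function(i) sample(universe))
  names(lib) <- sprintf("CP%04d", seq_len(n_compounds))
  if (!is.null(planted) && length(planted)) {
    if (is.null(query)) stop("planting requires a query signature")
    up <- intersect(query$up, universe)
    dn <- intersect(query$down, universe)
    mid <- setdiff(universe, c(up, dn))
    for (cp in names(planted)) {
      mode <- match.arg(planted[[cp]], c("mimic", "revert"))
      ranking <- if (mode == "mimic") c(up, sample(mid), dn)
                 else c(dn, sample(mid), up)
      lib[[cp]] <- ranking
    }
  }
  signature_library(lib)
}

#' Simulate an immune cell fraction matrix linked to a score
#'
#' Columns are Dirichlet draws; the concentration of linked cell types
#' varies log-linearly with the per-sample score:
#' `alpha_cs = alpha0_c * exp(crs_link_c * score_s)`.
#'
#' @param n_celltypes cell types (default 22, the leukocyte panel size).
#' @param n_samples samples.
#' @param crs_link per-cell-type log-linear coefficients (default all 0).
#' @param score per-sample driving score; standard normal draws when NULL.
#' @param seed master seed.
#' @return list: `fractions` (cell_type x sample, columns sum to 1),
#'   `score` (named).
#' @export
simulate_fractions <- function(n_celltypes = 22L, n_samples = 100L,
                               crs_link = rep(0, n_celltypes), score = NULL,
                               seed = 1L) {
  if (length(crs_link) != n_celltypes)
    stop("crs_link must have one coefficient per cell type")
  cts <- sprintf("CellType%02d", seq_len(n_celltypes))
  samples <- sprintf("S%04d", seq_len(n_samples))
  set.seed(.stream_seed(seed, "fractions"))
  alpha0 <- stats::runif(n_celltypes, 1, 5)
  if (is.null(score)) score <- stats::rnorm(n_samples)
  score <- stats::setNames(rep_len(score, n_samples), samples)
  frac <- vapply(seq_len(n_samples), function(s) {
    a <- alpha0 * exp(crs_link * score[s])
    g <- stats::rgamma(n_celltypes, shape = a, rate = 1)
    g / sum(g)
  }, numeric(n_celltypes))
  dimnames(frac) <- list(cts, samples)
  list(fractions = frac, score = score)
}
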