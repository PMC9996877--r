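# Tumor-vs-normal differential expression, unit conversion, and the
# SNV/CNV summaries.

#' Convert FPKM to TPM
#'
#' TPM_ij = FPKM_ij / sum_i FPKM_ij * 1e6, so every sample column sums
#' to one million.
#'
#' @param expr an [expression_matrix()] with unit `"FPKM"`.
#' @return an [expression_matrix()] with unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(expr) {
  if (expr_unit(expr) != "FPKM") stop("input unit must be FPKM")
  cs <- colSums(expr)
  if (any(cs <= 0)) stop("zero column sum; cannot rescale sample(s): ",
                         paste(colnames(expr)[cs <= 0], collapse = ", "))
  expression_matrix(sweep(unclass(expr), 2L, cs, "/") * 1e6, unit = "TPM")
}

#' Call differentially expressed genes between tumor and normal
#'
#' Per gene: log2 fold change = mean log2(tumor) - mean log2(normal)
#' (linear units get a +1 pseudocount before log2), two-sided Welch t
#' test on the log2 values, BH-adjusted q. A gene is called `up` when
#' fold change > `fc_thresh` and p < `p_thresh`, `down` when fold change
#' < 1/`fc_thresh` and p < `p_thresh`, otherwise `ns`. The gate uses the
#' raw p; q is reported alongside.
#'
#' @param tumor,normal [expression_matrix()] objects over the same gene
#'   universe (same unit), >= 2 samples each.
#' @param fc_thresh linear fold-change threshold (default 2).
#' @param p_thresh p-value threshold (default 0.05).
#' @return data.frame: `gene_id`, `log2_fc`, `p`, `q`, `call`.
#' @export
deg_call <- function(tumor, normal, fc_thresh = 2, p_thresh = 0.05) {
  if (!setequal(rownames(tumor), rownames(normal))) {
    d1 <- setdiff(rownames(tumor), rownames(normal))
    d2 <- setdiff(rownames(normal), rownames(tumor))
    stop("gene universes differ; tumor-only: ",
         paste(utils::head(d1, 5), collapse = ","),
         " normal-only: ", paste(utils::head(d2, 5), collapse = ","))
  }
  if (ncol(tumor) < 2L || ncol(normal) < 2L) stop("need >= 2 samples per side")
  normal <- normal[rownames(tumor), , drop = FALSE]
  to_log2 <- function(m) {
    if (expr_unit(m) == "log2") unclass(m) else log2(unclass(m) + 1)
  }
  lt <- to_log2(tumor); ln <- to_log2(normal)
  lfc <- rowMeans(lt) - rowMeans(ln)
  p <- vapply(seq_len(nrow(lt)), function(i) {
    a <- lt[i, ]; b <- ln[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1L))
  q <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", length(lfc))
  call[lfc > log2(fc_thresh) & p < p_thresh] <- "up"
  call[lfc < -log2(fc_thresh) & p < p_thresh] <- "down"
  data.frame(gene_id = rownames(tumor), log2_fc = unname(lfc), p = unname(p),
             q = unname(q), call = call, stringsAsFactors = FALSE)
}

#' Per-gene, per-cohort mutation frequency
#'
#' frequency(gene, cohort) = distinct mutated samples / cohort size.
#' Samples hit more than once in one gene count once, and their class
#' collapses to `multi_hit`. Also reports per-class counts and the
#' overall fraction of samples carrying >= 1 mutation.
#'
#' @param mut a `mutation_table` (needs the `cohort_sizes` attribute or
#'   `cohort_sizes` supplied here as a named vector).
#' @param cohort_sizes optional named integer vector overriding the
#'   attribute.
#' @param min_overall_freq optional display filter: keep only genes whose
#'   overall mutation proportion (distinct mutated samples / total cohort
#'   size) exceeds this value (the published displays use 0.1).
#' @return list: `frequency` (data.frame gene_id, cohort, n_mutated,
#'   cohort_size, freq), `class_counts` (named integer),
#'   `overall_mutated_fraction`, `sample_mutated` (named logical-ish
#'   0/1 per sample seen).
#' @export
mutation_frequency <- function(mut, cohort_sizes = NULL,
                               min_overall_freq = NULL) {
  if (is.null(cohort_sizes)) cohort_sizes <- attr(mut, "cohort_sizes")
  if (is.null(cohort_sizes)) stop("cohort sizes are required")
  df <- as.data.frame(mut)
  if (nrow(df) == 0L) {
    return(list(frequency = data.frame(gene_id = character(),
                                       cohort = character(),
                                       n_mutated = integer(),
                                       cohort_size = integer(),
                                       freq = numeric()),
                class_counts = stats::setNames(integer(length(VARIANT_CLASSES)),
                                               VARIANT_CLASSES),
                overall_mutated_fraction = 0,
                sample_mutated = integer()))
  }
  if (is.null(df$cohort)) df$cohort <- "all"
  df <- unique(df[c("sample_id", "gene_id", "variant_class", "cohort")])
  # collapse same sample x gene multi-hits
  key <- paste(df$sample_id, df$gene_id, df$cohort, sep = "\r")
  nhit <- table(key)
  multi <- names(nhit)[nhit > 1]
  df$variant_class[key %in% multi] <- "multi_hit"
  df <- unique(df[c("sample_id", "gene_id", "variant_class", "cohort")])
  freq <- do.call(rbind, lapply(split(df, list(df$gene_id, df$cohort),
                                      drop = TRUE), function(d) {
    co <- d$cohort[1L]
    n_mut <- length(unique(d$sample_id))
    cz <- cohort_sizes[[co]]
    if (is.null(cz) || is.na(cz)) stop("no declared size for cohort ", co)
    if (n_mut > cz) stop("cohort ", co, ": mutated samples exceed cohort size")
    data.frame(gene_id = d$gene_id[1L], cohort = co, n_mutated = n_mut,
               cohort_size = cz, freq = n_mut / cz,
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- NULL
  if (!is.null(min_overall_freq)) {
    total <- sum(cohort_sizes)
    overall <- tapply(df$sample_id, df$gene_id, function(s) length(unique(s)))
    keep <- names(overall)[overall / total > min_overall_freq]
    freq <- freq[freq$gene_id %in% keep, , drop = FALSE]
  }
  cc <- table(factor(df$variant_class, levels = VARIANT_CLASSES))
  n_mut_samples <- length(unique(df$sample_id))
  list(frequency = freq,
       class_counts = stats::setNames(as.integer(cc), VARIANT_CLASSES),
       overall_mutated_fraction = n_mut_samples / sum(cohort_sizes),
       sample_mutated = stats::setNames(rep(1L, n_mut_samples),
                                        unique(df$sample_id)))
}

#' Categorize CNV focal scores and summarize frequencies
#'
#' Scores > `hi` become 1 (amplification), < `lo` become -1 (deletion),
#' anything in [lo, hi] — the boundaries inclusive — is 0.
#'
#' @param cnv numeric gene x sample focal-score matrix.
#' @param lo,hi thresholds, default -0.3 / 0.3.
#' @return list: `categorized` (integer matrix in {-1,0,1}), `frequency`
#'   (data.frame gene_id, amp_freq, del_freq).
#' @export
cnv_categorize <- function(cnv, lo = -0.3, hi = 0.3) {
  if (lo >= hi) stop("lo must be < hi")
  cat <- matrix(0L, nrow = nrow(cnv), ncol = ncol(cnv), dimnames = dimnames(cnv))
  cat[cnv > hi] <- 1L
  cat[cnv < lo] <- -1L
  freq <- data.frame(gene_id = rownames(cnv),
                     amp_freq = rowMeans(cat == 1L),
                     del_freq = rowMeans(cat == -1L),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(categorized = cat, frequency = freq)
}

#' Per-gene Spearman correlation between CNV focal scores and expression
#'
#' Uses the raw (uncategorized) focal scores over the samples shared by
#' both matrices; genes with constant CNV get `NA` (undefined), not 0.
#'
#' @param cnv numeric gene x sample focal-score matrix.
#' @param expr an [expression_matrix()] over (a superset of) the same genes.
#' @return data.frame: `gene_id`, `rho`, `p`, `q` (BH over defined rows),
#'   `n`.
#' @export
cnv_expression_correlation <- function(cnv, expr) {
  shared_s <- intersect(colnames(cnv), colnames(expr))
  if (length(shared_s) < 5L) stop("needs >= 5 shared samples")
  shared_g <- intersect(rownames(cnv), rownames(expr))
  if (length(shared_g) == 0L) stop("no shared genes")
  res <- lapply(shared_g, function(g) {
    a <- cnv[g, shared_s]; b <- unclass(expr)[g, shared_s]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L)
      return(data.frame(gene_id = g, rho = NA_real_, p = NA_real_,
                        n = length(shared_s)))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    data.frame(gene_id = g, rho = unname(ct$estimate), p = ct$p.value,
               n = length(shared_s))
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out[c("gene_id", "rho", "p", "q", "n")]
}
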