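# CRS vs the immune microenvironment: cell-fraction group tests and
# correlation screens, stromal/immune signature scores, the
# immune-checkpoint gene screen, and therapy-response comparisons.

#' Wilcoxon group test per immune cell type
#'
#' Two-sided Wilcoxon rank-sum of each cell type's fractions between the
#' two score groups; significance flag at `p < alpha_level`.
#'
#' @param fractions cell_type x sample fraction matrix.
#' @param groups named (by sample) or aligned high/low labels.
#' @param alpha_level significance level for the flag (default 0.05).
#' @return data.frame: `cell_type`, `statistic`, `p`, `direction`
#'   (sign of median(high) - median(low)), `significant`.
#' @export
fraction_group_test <- function(fractions, groups, alpha_level = 0.05) {
  if (!is.null(names(groups))) {
    shared <- intersect(colnames(fractions), names(groups))
    fractions <- fractions[, shared, drop = FALSE]
    groups <- groups[shared]
  }
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  hi <- as.character(groups) == lev[1L]
  res <- lapply(rownames(fractions), function(ct) {
    a <- fractions[ct, hi]; b <- fractions[ct, !hi]
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(cell_type = ct, statistic = unname(ht$statistic),
               p = ht$p.value,
               direction = sign(stats::median(a) - stats::median(b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha_level
  attr(out, "reference_level") <- lev[1L]
  out
}

#' Spearman correlation of cell fractions with the CRS
#'
#' Per cell type, Spearman rho of fraction vs score over shared samples,
#' BH-adjusted across cell types. Cell types constant across samples are
#' dropped (undefined correlation), not reported as rho = 0.
#'
#' @param fractions cell_type x sample fraction matrix.
#' @param crs named numeric scores (names = sample ids) or a `crs_table`.
#' @return data.frame: `feature_id`, `rho`, `p`, `q`, `n`.
#' @export
fraction_crs_correlation <- function(fractions, crs) {
  crs <- as_named_scores(crs)
  shared <- intersect(colnames(fractions), names(crs))
  if (length(shared) < 5L) stop("needs >= 5 shared samples")
  correlation_screen(fractions[, shared, drop = FALSE], crs[shared],
                     method = "spearman")
}

# shared feature x sample vs score correlation screen
correlation_screen <- function(m, score, method = "spearman") {
  res <- lapply(rownames(m), function(f) {
    v <- m[f, ]
    if (length(unique(v)) < 2L) return(NULL)
    ct <- suppressWarnings(stats::cor.test(v, score, method = method))
    data.frame(feature_id = f, rho = unname(ct$estimate), p = ct$p.value,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) stop("no feature with defined correlation")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[c("feature_id", "rho", "p", "q", "n")]
}

as_named_scores <- function(crs) {
  if (inherits(crs, "crs_table") ||
      (is.data.frame(crs) && all(c("sample_id", "crs") %in% colnames(crs))))
    return(stats::setNames(crs$crs, crs$sample_id))
  if (is.null(names(crs))) stop("scores must be named by sample id")
  crs
}

#' Stromal / immune signature scores
#'
#' Unnormalized ssGSEA enrichment of a stromal and an immune signature in
#' one shared call; `estimate = stromal + immune` exactly. Optionally
#' emits a tumor-purity transform,
#' `purity = cos(0.6049872018 + 0.0001467884 * estimate)` clipped to
#' [0, 1] — the constants come from the original ESTIMATE publication and
#' are only meaningful on ESTIMATE's own scale, hence opt-in.
#'
#' @param expr an [expression_matrix()].
#' @param stromal_set,immune_set character gene sets.
#' @param alpha ssGSEA exponent.
#' @param purity emit the ESTIMATE-style purity column (default FALSE).
#' @return data.frame: `sample_id`, `stromal`, `immune`, `estimate`
#'   (+ `purity` when requested).
#' @export
signature_scores <- function(expr, stromal_set, immune_set, alpha = 0.25,
                             purity = FALSE) {
  sc <- ssgsea_score(expr, list(stromal = stromal_set, immune = immune_set),
                     alpha = alpha, normalize = FALSE)
  out <- data.frame(sample_id = colnames(expr),
                    stromal = unname(sc["stromal", ]),
                    immune = unname(sc["immune", ]),
                    stringsAsFactors = FALSE)
  out$estimate <- out$stromal + out$immune
  if (purity)
    out$purity <- pmin(1, pmax(0, cos(0.6049872018 + 0.0001467884 * out$estimate)))
  out
}

#' Immune-checkpoint gene screen against the CRS
#'
#' Correlates each checkpoint gene's expression with the CRS (Spearman by
#' default; Pearson exposed as an option) and keeps genes with
#' |rho| > `r_thresh` and p < `p_thresh`.
#'
#' @param expr an [expression_matrix()].
#' @param crs named scores or `crs_table`.
#' @param icg_genes character vector of checkpoint genes (or a
#'   `gene_set_collection`; all sets are pooled). Genes absent from the
#'   matrix are reported in the `missing_genes` attribute.
#' @param r_thresh,p_thresh screen thresholds (defaults 0.7, 0.05).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame of passing genes: `feature_id`, `rho`, `p`, `q`,
#'   `n`, `direction`; attribute `all_records` keeps the unfiltered screen.
#' @export
icg_screen <- function(expr, crs, icg_genes = NULL, r_thresh = 0.7,
                       p_thresh = 0.05, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(icg_genes)) icg_genes <- icg_gene_sets()
  if (is.list(icg_genes)) icg_genes <- unique(unlist(icg_genes))
  crs <- as_named_scores(crs)
  shared <- intersect(colnames(expr), names(crs))
  if (length(shared) < 5L) stop("needs >= 5 shared samples")
  present <- intersect(icg_genes, rownames(expr))
  missing <- setdiff(icg_genes, rownames(expr))
  if (length(present) == 0L) stop("no immune checkpoint gene present in matrix")
  rec <- correlation_screen(unclass(expr)[present, shared, drop = FALSE],
                            crs[shared], method = method)
  hits <- rec[abs(rec$rho) > r_thresh & rec$p < p_thresh, , drop = FALSE]
  hits$direction <- ifelse(hits$rho > 0, "positive", "negative")
  rownames(hits) <- NULL
  attr(hits, "all_records") <- rec
  attr(hits, "missing_genes") <- missing
  attr(hits, "method") <- method
  hits
}

#' Compare CRS between therapy-response groups
#'
#' Two-sided Wilcoxon rank-sum between the two label groups (e.g.
#' responder vs non-responder, treated vs control) plus the direction of
#' the median difference.
#'
#' @param crs named scores or `crs_table`.
#' @param response per-sample labels (named by sample id when `crs` is
#'   named).
#' @return list: `statistic`, `p`, `direction` (level with the lower
#'   median), `median_diff`, `levels`.
#' @export
response_compare <- function(crs, response) {
  crs <- as_named_scores(crs)
  if (!is.null(names(response))) {
    shared <- intersect(names(crs), names(response))
    crs <- crs[shared]; response <- response[shared]
  }
  lev <- sort(unique(as.character(response)))
  if (length(lev) != 2L) stop("response must have exactly two levels")
  if (min(table(response)) < 2L) stop("need >= 2 samples per response group")
  a <- crs[response == lev[1L]]; b <- crs[response == lev[2L]]
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  md <- stats::median(a) - stats::median(b)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       direction = if (md < 0) lev[1L] else lev[2L],
       median_diff = md, levels = lev)
}
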