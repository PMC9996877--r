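# Connectivity-map style compound screening: build CRS-correlated query
# signatures and score compound rankings with a bidirectional
# Kolmogorov-Smirnov statistic.

#' Build the CRS query signature for one cohort
#'
#' Per-gene Spearman correlation of expression with the CRS; the query is
#' the `n_top` most positively correlated genes (`up`) and the `n_top`
#' most negatively correlated (`down`). Equal correlations are broken
#' lexicographically by gene id, so repeat runs are identical.
#'
#' @param expr an [expression_matrix()].
#' @param crs named scores or `crs_table`.
#' @param n_top genes per tail (default 150).
#' @param strict error (TRUE) or warn-and-truncate (FALSE, default) when
#'   fewer than `2 * n_top` genes have a defined correlation.
#' @return list of class `query_signature`: `up`, `down` (ordered,
#'   strongest first), `n_top`, `rho` (full named vector).
#' @export
crs_gene_signature <- function(expr, crs, n_top = 150L, strict = FALSE) {
  crs <- as_named_scores(crs)
  shared <- intersect(colnames(expr), names(crs))
  if (length(shared) < 5L) stop("needs >= 5 samples")
  m <- unclass(expr)[, shared, drop = FALSE]
  s <- crs[shared]
  rs <- rank(s, ties.method = "average")
  rho <- apply(m, 1L, function(v) {
    if (length(unique(v)) < 2L) return(NA_real_)
    stats::cor(rank(v, ties.method = "average"), rs)
  })
  rho <- rho[!is.na(rho)]
  if (length(rho) < 2L * n_top) {
    msg <- sprintf("only %d genes with defined correlation for 2 x n_top = %d",
                   length(rho), 2L * n_top)
    if (strict) stop(msg)
    warning(msg, "; truncating tails")
    n_top <- length(rho) %/% 2L
  }
  ord_up <- order(-rho, names(rho))
  ord_dn <- order(rho, names(rho))
  structure(list(up = names(rho)[ord_up][seq_len(n_top)],
                 down = names(rho)[ord_dn][seq_len(n_top)],
                 n_top = n_top, rho = rho),
            class = "query_signature")
}

# one-sided KS running statistic for a tag set within a ranking of n genes.
# positions: sorted 1-based positions of the tags. Returns a if a > b
# else -b (the tie a == b resolves to -b).
.ks_tag <- function(positions, n) {
  t <- length(positions)
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Bidirectional KS connectivity score of one compound
#'
#' ks(up) and ks(down) are one-sided Kolmogorov-Smirnov statistics of the
#' query tails' positions within the compound's ranking; the raw score is
#' `s = ks(up) - ks(down)`, set to 0 when both tails drift to the same
#' end (shared sign). Query genes absent from the compound's universe are
#' dropped per compound with a warning.
#'
#' @param query a `query_signature` (or list with `up`, `down`).
#' @param ranking character vector: the compound's genes ordered from
#'   most up-regulated (rank 1) to most down-regulated.
#' @return scalar raw connectivity in [-2, 2], with attributes `ks_up`,
#'   `ks_down`.
#' @export
ks_connectivity <- function(query, ranking) {
  n <- length(ranking)
  pos <- function(tags, label) {
    p <- match(tags, ranking)
    if (anyNA(p)) {
      warning(sum(is.na(p)), " ", label, "-tag gene(s) absent from ranking; dropped")
      p <- p[!is.na(p)]
    }
    if (length(p) == 0L) stop("empty ", label, " tag set after dropping")
    sort(p)
  }
  ks_up <- .ks_tag(pos(query$up, "up"), n)
  ks_dn <- .ks_tag(pos(query$down, "down"), n)
  s <- if (sign(ks_up) == sign(ks_dn) && sign(ks_up) != 0) 0 else ks_up - ks_dn
  structure(s, ks_up = ks_up, ks_down = ks_dn)
}

#' Scale raw connectivity scores to [-100, 100] within one cohort
#'
#' With p = max positive raw score and q = min negative raw score of the
#' cohort: positive scores map to 100 s / p, negative to -100 s / q,
#' zero stays zero. Sign-preserving and order-preserving within each
#' sign; idempotent when the extremes are already +-100.
#'
#' @param raw named numeric raw scores (one cohort / cancer type).
#' @return named numeric scores in [-100, 100].
#' @export
scale_scores <- function(raw) {
  if (length(raw) == 0L) stop("needs >= 1 compound")
  out <- raw
  pos <- raw > 0; neg <- raw < 0
  if (any(pos)) out[pos] <- 100 * raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- -100 * raw[neg] / min(raw[neg])
  out[raw == 0] <- 0
  out
}

#' Score a whole signature library against one query
#'
#' @param query a `query_signature`.
#' @param library_ a `signature_library` (named list of rankings).
#' @param scale return per-cohort scaled scores (default TRUE).
#' @return named numeric vector of scores, one per compound.
#' @export
score_library <- function(query, library_, scale = TRUE) {
  raw <- vapply(library_, function(rk) as.numeric(ks_connectivity(query, rk)),
                numeric(1L))
  if (scale) scale_scores(raw) else raw
}

#' Screen the compound x cancer connectivity matrix for consistent hits
#'
#' A compound is a positive hit when its scaled score exceeds `thresh` in
#' at least `min_cancers` cancer types, a negative hit when it is below
#' `-thresh` in at least `min_cancers`. Missing cells count as non-hits.
#'
#' @param conn compound x cancer numeric matrix of scaled scores.
#' @param thresh score threshold (default 90).
#' @param min_cancers minimum supporting cancer types (default 10).
#' @return list: `positive`, `negative` (compound ids), `n_positive_cancers`,
#'   `n_negative_cancers` (named counts).
#' @export
compound_screen <- function(conn, thresh = 90, min_cancers = 10L) {
  npos <- rowSums(conn > thresh, na.rm = TRUE)
  nneg <- rowSums(conn < -thresh, na.rm = TRUE)
  list(positive = rownames(conn)[npos >= min_cancers],
       negative = rownames(conn)[nneg >= min_cancers],
       n_positive_cancers = npos, n_negative_cancers = nneg)
}
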