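# Rank-based single-sample gene-set enrichment (ssGSEA).
#
# Per sample, genes are ranked by expression (highest expression = rank N)
# and the enrichment score is the integrated difference between the
# rank-weighted cumulative distribution of the in-set genes and the
# unweighted cumulative distribution of the out-of-set genes.

#' Per-sample rank transform
#'
#' Ranks each sample column ascending in expression: the most highly
#' expressed gene gets rank N. Ties receive average (fractional) ranks.
#'
#' @param expr an [expression_matrix()] (any unit) or numeric matrix with
#'   gene row names; needs at least 2 genes.
#' @return gene x sample matrix of ranks with attribute `ties = "average"`.
#' @export
rank_transform <- function(expr) {
  if (nrow(expr) < 2L)
    stop("rank transform needs >= 2 genes; enrichment is undefined otherwise")
  r <- apply(unclass(expr), 2L, rank, ties.method = "average")
  dimnames(r) <- dimnames(expr)
  attr(r, "ties") <- "average"
  r
}

# ES for one sample column of ranks. Walk order is decreasing rank;
# ties in the walk are broken by row order (stable), which is
# deterministic for a fixed gene ordering.
.es_one_sample <- function(r, in_set, alpha) {
  n <- length(r)
  ord <- order(-r)
  hit <- in_set[ord]
  w <- r[ord]^alpha * hit
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / (n - sum(in_set))
  sum(p_hit - p_miss)
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' For each sample, with genes ordered by decreasing rank r and tag set S:
#' \deqn{P_{hit}(k) = \sum_{i \in S, pos(i) \le k} r_i^\alpha / \sum_{i \in S} r_i^\alpha,
#'       \quad P_{miss}(k) = |\{i \notin S: pos(i) \le k\}| / (N - |S|)}
#' and \eqn{ES = \sum_k (P_{hit}(k) - P_{miss}(k))}.
#'
#' With `normalize = TRUE` every ES is divided by the (max - min) range of
#' the full score matrix of the call — all sets and all samples jointly —
#' so scores from one call share a scale.
#'
#' @param expr an [expression_matrix()] or numeric matrix with gene rownames.
#' @param gene_sets a character vector (one set) or named list of character
#'   vectors. Genes absent from the matrix are dropped with a warning.
#' @param alpha rank-weighting exponent; `0.25` is the canonical ssGSEA
#'   choice, `0` weights all in-set genes equally.
#' @param normalize divide by the joint score range of the call.
#' @return set x sample numeric matrix of scores, with attributes `alpha`,
#'   `normalized` and (when normalized) `normalization_constant`.
#' @export
ssgsea_score <- function(expr, gene_sets, alpha = 0.25, normalize = FALSE) {
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  if (alpha < 0) stop("alpha must be >= 0")
  genes <- rownames(expr)
  n <- length(genes)
  r <- rank_transform(expr)
  scores <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(expr),
                   dimnames = list(names(gene_sets), colnames(expr)))
  for (s in seq_along(gene_sets)) {
    set <- unique(gene_sets[[s]])
    missing <- setdiff(set, genes)
    if (length(missing))
      warning("set '", names(gene_sets)[s], "': ", length(missing),
              " gene(s) absent from the matrix dropped: ",
              paste(missing, collapse = ", "))
    set <- intersect(set, genes)
    if (length(set) == 0L)
      stop("set '", names(gene_sets)[s], "' has no genes in the matrix")
    if (length(set) == n)
      stop("set '", names(gene_sets)[s],
           "' covers every gene; the complement is empty")
    in_set <- genes %in% set
    scores[s, ] <- apply(r, 2L, .es_one_sample, in_set = in_set, alpha = alpha)
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng <= 0)
      stop("cannot normalize: score range of the call is not positive")
    scores <- scores / rng
    attr(scores, "alpha") <- alpha
    attr(scores, "normalized") <- TRUE
    attr(scores, "normalization_constant") <- rng
  }
  scores
}

#' Score a clock-control / core-clock pair with shared normalization
#'
#' Scores both sets of the pair in a single ssGSEA call so that, when
#' normalized, they share one normalization constant and their difference
#' (the CRS) is on a common scale.
#'
#' @param expr an [expression_matrix()].
#' @param pair a [gene_set_pair()], or any list with character elements
#'   `control` and `core` (disjointness is enforced only for the former).
#' @inheritParams ssgsea_score
#' @return list with `control` and `core` named score vectors (per sample)
#'   plus `alpha`, `normalized`, `normalization_constant`.
#' @export
score_pair <- function(expr, pair, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.list(pair), !is.null(pair$control), !is.null(pair$core))
  m <- ssgsea_score(expr, list(control = pair$control, core = pair$core),
                    alpha = alpha, normalize = normalize)
  list(control = m["control", ], core = m["core", ],
       alpha = alpha, normalized = normalize,
       normalization_constant = attr(m, "normalization_constant"))
}
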