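# Independent brute-force oracles. Deliberately written with plain loops
# and (where possible) third-party routines so they share no code path
# with the implementation they check.

# Direct-summation ssGSEA for a single sample given named expression
# values. Loops over walk positions explicitly.
oracle_ssgsea_one <- function(values, set, alpha) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  ord <- names(sort(r, decreasing = TRUE))  # walk order: decreasing rank
  in_set <- ord %in% set
  denom_hit <- sum(r[ord][in_set]^alpha)
  n_miss <- n - sum(in_set)
  es <- 0
  hit_acc <- 0
  miss_acc <- 0
  for (k in seq_len(n)) {
    if (in_set[k]) hit_acc <- hit_acc + r[ord[k]]^alpha
    else miss_acc <- miss_acc + 1
    es <- es + hit_acc / denom_hit - miss_acc / n_miss
  }
  unname(es)
}

# Exhaustive cutpoint scan using survival::survdiff for the statistic.
oracle_cutpoint <- function(values, time, event, minprop = 0.1) {
  n <- length(values)
  cand <- sort(unique(values))
  best <- NULL
  for (cp in cand) {
    high <- values > cp
    if (sum(high) < minprop * n || sum(!high) < minprop * n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ high)
    z <- sqrt(sd$chisq)
    if (is.null(best) || z > best$z + 1e-12) best <- list(cp = cp, z = z)
  }
  best
}

# Direct one-sided KS tag statistic by explicit loops over j.
oracle_ks_tag <- function(positions, n) {
  positions <- sort(positions)
  t <- length(positions)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - positions[j] / n)
    b <- max(b, positions[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

oracle_ks_connectivity <- function(up_pos, down_pos, n) {
  ku <- oracle_ks_tag(up_pos, n)
  kd <- oracle_ks_tag(down_pos, n)
  if (sign(ku) == sign(kd) && sign(ku) != 0) 0 else ku - kd
}

# Random small expression fixture with unique values
random_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, unit = "log2")
}

random_survival <- function(n, seed, censor = 0.3) {
  set.seed(seed)
  list(time = rexp(n, 0.1) + 0.01,
       event = as.integer(runif(n) > censor),
       x = rnorm(n))
}
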