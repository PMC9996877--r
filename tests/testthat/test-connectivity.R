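test_that("signature builder picks the correlation tails deterministically", {
  set.seed(71)
  crs <- setNames(seq(-2, 2, length.out = 20), sprintf("s%02d", 1:20))
  m <- rbind(g1 = crs * 2, g2 = rnorm(20), g3 = -crs)
  colnames(m) <- names(crs)
  e <- expression_matrix(m, unit = "log2")
  suppressWarnings(sig <- crs_gene_signature(e, crs, n_top = 1))
  expect_identical(sig$up, "g1")
  expect_identical(sig$down, "g3")
  # negating the score swaps the tails exactly
  suppressWarnings(sig2 <- crs_gene_signature(e, -crs, n_top = 1))
  expect_identical(sig2$up, sig$down)
  expect_identical(sig2$down, sig$up)
})

test_that("KS connectivity matches hand values and the enumeration oracle", {
  # n = 4, t = 1, tag at position 2: a = 1 - 2/4 = 0.5 = b, tie -> -b
  expect_equal(as.numeric(crscore:::.ks_tag(2L, 4L)), -0.5)
  # extreme construction: up tags on top, down tags at the bottom
  ranking <- sprintf("g%02d", 1:20)
  q <- list(up = ranking[1:3], down = ranking[18:20])
  # t tags on top: a peaks at j = t, a = t/t - t/n = 1 - t/n; t tags at the
  # bottom: b peaks at j = 1, b = (n-t+1)/n - 0 = 1 - (t-1)/n
  s <- ks_connectivity(q, ranking)
  expect_equal(attr(s, "ks_up"), 1 - 3 / 20)
  expect_equal(attr(s, "ks_down"), -(1 - 2 / 20))
  expect_equal(as.numeric(s), (1 - 3 / 20) + (1 - 2 / 20))
  # exhaustive small instances against the loop oracle
  for (n in c(6L, 9L, 12L)) {
    for (t in 1:3) {
      combs <- utils::combn(n, t)
      for (i in seq_len(ncol(combs))) {
        pos <- combs[, i]
        expect_equal(as.numeric(crscore:::.ks_tag(pos, n)),
                     oracle_ks_tag(pos, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("ranking reversal anti-symmetry holds up to discretization", {
  # For the discrete running statistic, reversing a ranking maps the two
  # one-sided maxima onto each other only up to offsets of order 1/t and
  # 1/n, so negation is exact only in the continuous limit. Verify the
  # implementation against the enumeration oracle on both orientations
  # and the negation at the discretization tolerance.
  set.seed(72)
  for (rep in 1:25) {
    n <- sample(10:20, 1)
    ranking <- sample(sprintf("g%02d", 1:n))
    t <- sample(1:4, 1)
    picks <- sample(ranking, 2 * t)
    q <- list(up = picks[1:t], down = picks[(t + 1):(2 * t)])
    s_fwd <- as.numeric(ks_connectivity(q, ranking))
    s_rev <- as.numeric(ks_connectivity(q, rev(ranking)))
    pos <- function(tags, rk) sort(match(tags, rk))
    expect_equal(s_fwd, oracle_ks_connectivity(pos(q$up, ranking),
                                               pos(q$down, ranking), n),
                 tolerance = 1e-12)
    expect_equal(s_rev, oracle_ks_connectivity(pos(q$up, rev(ranking)),
                                               pos(q$down, rev(ranking)), n),
                 tolerance = 1e-12)
    if (s_fwd != 0 && s_rev != 0)
      expect_lte(abs(s_rev + s_fwd), 2 * (1 / t + 1 / n) + 1e-12)
    # swapping up and down negates exactly (true antisymmetry)
    s_swap <- as.numeric(ks_connectivity(list(up = q$down, down = q$up),
                                         ranking))
    expect_equal(s_swap, -s_fwd, tolerance = 1e-12)
  }
})

test_that("same-sign tails collapse to zero and absent genes are dropped", {
  ranking <- sprintf("g%02d", 1:20)
  both_top <- list(up = ranking[1:3], down = ranking[4:6])
  expect_equal(as.numeric(ks_connectivity(both_top, ranking)), 0)
  q <- list(up = c(ranking[1], "ABSENT"), down = ranking[19:20])
  expect_warning(s <- ks_connectivity(q, ranking), "absent from ranking")
  expect_gt(as.numeric(s), 0)
  expect_error(
    suppressWarnings(ks_connectivity(list(up = "ABSENT", down = ranking[20]),
                                     ranking)),
    "empty up")
})

test_that("score scaling maps extremes to +-100 and preserves order", {
  raw <- c(a = 2, b = 1, c = -1)
  expect_equal(unname(scale_scores(raw)), c(100, 50, -100))
  expect_equal(unname(scale_scores(c(x = 3, y = 3))), c(100, 100))
  scaled <- scale_scores(raw)
  expect_equal(scale_scores(scaled), scaled)  # idempotent at +-100 extremes
  set.seed(73)
  r <- rnorm(50)
  s <- scale_scores(r)
  expect_true(all(diff(s[order(r)][r[order(r)] > 0]) >= -1e-12))
  expect_true(all(s >= -100 & s <= 100))
})

test_that("compound screen applies both the score and the cancer-count gates", {
  conn <- matrix(0, nrow = 3, ncol = 18,
                 dimnames = list(c("hit", "almost", "anti"), NULL))
  conn["hit", 1:10] <- 95
  conn["almost", 1:9] <- 95
  conn["anti", 1:12] <- -95
  sc <- compound_screen(conn, thresh = 90, min_cancers = 10)
  expect_identical(sc$positive, "hit")
  expect_identical(sc$negative, "anti")
  # exactly at the threshold score does not count (strict >)
  conn["hit", 1:10] <- 90
  expect_length(compound_screen(conn)$positive, 0L)
})
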