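test_that("Kaplan-Meier matches hand-derived product-limit fixtures", {
  # events at 1, 2, 3, no censoring
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored
  expect_true(all(km_curve(c(1, 2, 3), c(0, 0, 0))$survival == 1))
  # (1,event), (2,censor), (3,event): S(1)=2/3, S(3)=2/3*(1-1/1)=0
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
  expect_error(km_curve(numeric(0), integer(0)), "empty")
})

test_that("Kaplan-Meier agrees with survival::survfit and the ECDF without censoring", {
  d <- random_survival(80, seed = 2)
  km <- km_curve(d$time, d$event)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  expect_equal(km$survival, summary(sf, times = km$time)$surv,
               tolerance = 1e-10)
  # no censoring: product-limit equals the empirical survival function
  km2 <- km_curve(d$time, rep(1L, 80))
  expect_equal(km2$survival, 1 - ecdf(d$time)(km2$time), tolerance = 1e-12)
})

test_that("log-rank: null fixture, symmetry, agreement with survdiff", {
  d <- random_survival(40, seed = 3)
  # duplicated groups: identical survival experience, chi2 exactly 0
  lr <- logrank_test(rep(d$time, 2), rep(d$event, 2),
                     rep(c("a", "b"), each = 40))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  g <- rep(c("a", "b"), 20)
  lr1 <- logrank_test(d$time, d$event, g)
  lr2 <- logrank_test(d$time, d$event, ifelse(g == "a", "b", "a"))
  expect_equal(lr1$chi2, lr2$chi2, tolerance = 1e-12)
  sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
  expect_equal(lr1$chi2, sd$chisq, tolerance = 1e-8)
  expect_error(logrank_test(d$time, rep(0, 40), g), "event")
})

test_that("log-rank four-time fixture matches the summed-variance hand formula", {
  time <- c(1, 2, 3, 4); event <- rep(1, 4); g <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, g)
  # O1 = 2; E1 = 2/4 + 1/3 + 0 + 0 = 5/6
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6, tolerance = 1e-12)
  # V = sum d(n1/n)(1-n1/n)(n-d)/(n-1): t=1: (2/4)(2/4)(3/3)=1/4;
  # t=2: (1/3)(2/3)(2/2)=2/9; t=3,4: n1=0 -> 0
  V <- 1 / 4 + 2 / 9
  expect_equal(lr$variance, V, tolerance = 1e-12)
  expect_equal(lr$chi2, (2 - 5 / 6)^2 / V, tolerance = 1e-10)
})

test_that("log-rank p under permuted labels is uniform", {
  d <- random_survival(60, seed = 4)
  set.seed(99)
  ps <- replicate(300, {
    g <- sample(rep(c("a", "b"), 30))
    logrank_test(d$time, d$event, g)$p
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.1)
})

test_that("optimal cutpoint equals the exhaustive-scan oracle", {
  for (rep in 1:40) {
    set.seed(rep)
    n <- sample(15:40, 1)
    v <- rnorm(n)
    d <- random_survival(n, seed = 1000 + rep)
    got <- optimal_cutpoint(v, d$time, d$event, minprop = 0.1)
    want <- oracle_cutpoint(v, d$time, d$event, minprop = 0.1)
    expect_equal(got$cutpoint, want$cp)
    expect_equal(got$max_abs_standardized_statistic, want$z, tolerance = 1e-8)
  }
})

test_that("cutpoint scan is rank-based and respects minprop", {
  set.seed(8)
  v <- rnorm(40)
  d <- random_survival(40, seed = 8)
  a <- optimal_cutpoint(v, d$time, d$event)
  b <- optimal_cutpoint(exp(v), d$time, d$event)  # monotone transform
  expect_identical(v > a$cutpoint, exp(v) > b$cutpoint)
  expect_true(all(vapply(a$candidates, function(cp)
    min(sum(v > cp), sum(v <= cp)) >= 0.1 * 40, logical(1))))
  # events concentrated in the top half of the marker: cutpoint sits at the
  # boundary between the two order-statistic blocks
  v2 <- 1:20
  t2 <- c(rep(100, 10), 1:10)
  e2 <- c(rep(0, 10), rep(1, 10))
  cut2 <- optimal_cutpoint(v2, t2, e2, minprop = 0.1)
  expect_gte(cut2$cutpoint, 10)
  expect_lt(cut2$cutpoint, 11)
})

test_that("Cox matches coxph with Breslow ties on random data", {
  for (rep in 1:10) {
    d <- random_survival(60, seed = 2000 + rep)
    x <- d$x + 0.5 * d$event
    got <- cox_univariate(x, d$time, d$event)
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ x,
                           ties = "breslow")
    expect_equal(got$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(got$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
    expect_true(got$converged)
  }
})

test_that("Cox flags degenerate inputs instead of silently estimating", {
  d <- random_survival(30, seed = 5)
  expect_error(cox_univariate(rep(1, 30), d$time, d$event), "constant")
  # perfect separation: covariate is the event time order, monotone likelihood
  t <- 1:20
  r <- cox_univariate(-t, t, rep(1, 20))
  expect_false(r$flag == "ok" && abs(r$beta) < 20)
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square", {
  d <- list(time = c(0.5, 1.2, 2.3, 3.1, 4.5, 5.2, 6.1, 7.4, 8.2, 9.9),
            event = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1))
  g <- rep(c(0, 1), 5)
  sc <- cox_score_test(g, d$time, d$event)
  lr <- logrank_test(d$time, d$event, ifelse(g == 1, "a", "b"))
  expect_equal(sc, lr$chi2, tolerance = 1e-8)
})

test_that("Cox recovers a simulated hazard coefficient and direction matches log-rank", {
  betas <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_params(n_genes_background = 50L,
                                        n_tumor = 150L, n_normal = 2L,
                                        hazard_beta = 0.8, seed = 3000L + s))
    cox_univariate(co$true_score[co$clinical$sample_id],
                   co$clinical$os_time_days, co$clinical$os_event)$beta
  }, numeric(1))
  expect_gt(mean(betas), 0.8 - 0.15)
  expect_lt(mean(betas), 0.8 + 0.15)
})
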