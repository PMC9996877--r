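# Survival machinery implemented from first principles: product-limit
# curves, two-group log-rank, maximally selected rank-statistic cutpoint,
# univariate Cox by Newton-Raphson with Breslow ties.

#' Kaplan-Meier product-limit curve
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i). Censored-only
#' times reduce the risk set but leave S unchanged.
#'
#' @param time positive survival/censoring times.
#' @param event 0 = censored, 1 = event.
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` (non-increasing, starts
#'   from S(0) = 1).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (length(time) == 0L) stop("empty group")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  tt <- sort(unique(time))
  n <- length(time)
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1L))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), numeric(1L))
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0), numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

# O1, E1, V of the two-group log-rank over distinct event times
# (hypergeometric variance). group is logical: TRUE = group 1.
.logrank_oev <- function(time, event, group) {
  dt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in dt) {
    at <- time >= t
    nj <- sum(at)
    n1j <- sum(at & group)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & group)
    O1 <- O1 + d1j
    E1 <- E1 + dj * n1j / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  c(O1 = O1, E1 = E1, V = V)
}

#' Two-group log-rank test
#'
#' chi^2 = (O1 - E1)^2 / V with the hypergeometric variance summed over
#' distinct event times; p from chi-square with 1 df.
#'
#' @param time positive times.
#' @param event 0/1 indicators.
#' @param group two-level labels.
#' @return list: `chi2`, `p`, `observed`, `expected` (group-1 totals),
#'   `variance`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L) stop("log-rank needs exactly two groups")
  if (sum(event == 1) == 0L) stop("log-rank needs >= 1 event")
  g1 <- as.character(group) == lev[1L]
  oev <- .logrank_oev(time, event, g1)
  chi2 <- if (oev["V"] > 0) (oev["O1"] - oev["E1"])^2 / oev["V"] else 0
  list(chi2 = unname(chi2),
       p = stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE),
       observed = unname(oev["O1"]), expected = unname(oev["E1"]),
       variance = unname(oev["V"]))
}

#' Optimal cutpoint by maximally selected rank statistics
#'
#' Scans the observed marker values whose induced split (`> c` = high)
#' leaves at least `minprop * n` samples on each side, computes the
#' standardized two-group log-rank statistic at every candidate, and
#' returns the candidate with the largest absolute statistic. Ties break
#' toward the smaller cutpoint. The statistic at the selected cutpoint is
#' selection-biased; downstream p-values from it carry an explicit
#' `selection_biased` flag and no correction is applied.
#'
#' @param values per-sample marker (e.g. CRS).
#' @param time,event survival data aligned with `values`.
#' @param minprop minimum proportion of samples per side (default 0.1).
#' @return list of class `cutpoint_result`: `cutpoint`,
#'   `max_abs_standardized_statistic`, `candidates`, `statistics`,
#'   `minprop`, `selection_biased = TRUE`.
#' @export
optimal_cutpoint <- function(values, time, event, minprop = 0.1) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  n <- length(values)
  if (sum(event == 1) == 0L) stop("needs >= 1 event")
  cand <- sort(unique(values))
  lo <- minprop * n
  admissible <- vapply(cand, function(cp) {
    nh <- sum(values > cp)
    nh >= lo && (n - nh) >= lo
  }, logical(1L))
  cand <- cand[admissible]
  if (length(cand) == 0L) stop("no admissible candidate cutpoint at minprop = ",
                               minprop)
  z <- vapply(cand, function(cp) {
    oev <- .logrank_oev(time, event, values > cp)
    if (oev["V"] <= 0) return(0)
    unname((oev["O1"] - oev["E1"]) / sqrt(oev["V"]))
  }, numeric(1L))
  best <- which.max(abs(z))   # which.max takes the first = smallest candidate
  structure(list(cutpoint = cand[best],
                 max_abs_standardized_statistic = abs(z[best]),
                 candidates = cand, statistics = z, minprop = minprop,
                 selection_biased = TRUE),
            class = "cutpoint_result")
}

#' Stratify samples at a cutpoint
#'
#' Samples with `values > cutpoint` are labelled `"high"`, the rest
#' `"low"` — matching the CRS-high / CRS-low usage.
#'
#' @param values numeric marker.
#' @param cutpoint threshold (e.g. from [optimal_cutpoint()]).
#' @return character vector of `"high"`/`"low"`.
#' @export
stratify_at_cutpoint <- function(values, cutpoint) {
  ifelse(values > cutpoint, "high", "low")
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson from
#' beta = 0; converges when |delta beta| < 1e-8 (at most `max_iter`
#' iterations). Reports beta, SE from the observed information, Wald
#' z/p and the 95% CI of the hazard ratio. Monotone likelihoods
#' (perfect separation) and non-convergence are flagged, not returned
#' as silent estimates.
#'
#' @param x per-sample numeric covariate (non-constant).
#' @param time,event survival data.
#' @param max_iter Newton-Raphson iteration cap.
#' @return list of class `cox_result`: `beta`, `hr`, `se`, `z`, `p`,
#'   `ci95`, `iterations`, `converged`, `flag` (`"ok"`,
#'   `"monotone_likelihood"` or `"not_converged"`), `ties = "breslow"`.
#' @export
cox_univariate <- function(x, time, event, max_iter = 50L) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (sum(event == 1) < 2L) stop("needs >= 2 events")
  if (length(unique(x)) < 2L) stop("covariate is constant")
  dt <- sort(unique(time[event == 1]))
  d <- vapply(dt, function(t) sum(time == t & event == 1), numeric(1L))
  xsum <- vapply(dt, function(t) sum(x[time == t & event == 1]), numeric(1L))
  risk_idx <- lapply(dt, function(t) which(time >= t))
  beta <- 0
  converged <- FALSE
  flag <- "ok"
  for (it in seq_len(max_iter)) {
    U <- 0; I <- 0
    for (j in seq_along(dt)) {
      xr <- x[risk_idx[[j]]]
      w <- exp(beta * xr)
      s0 <- sum(w); s1 <- sum(w * xr); s2 <- sum(w * xr^2)
      U <- U + xsum[j] - d[j] * s1 / s0
      I <- I + d[j] * (s2 / s0 - (s1 / s0)^2)
    }
    if (I <= .Machine$double.eps) { flag <- "monotone_likelihood"; break }
    step <- U / I
    beta <- beta + step
    if (abs(beta) > 50) { flag <- "monotone_likelihood"; break }
    if (abs(step) < 1e-8) { converged <- TRUE; break }
  }
  if (!converged && flag == "ok") flag <- "not_converged"
  # information at the final beta for the SE
  I <- 0
  for (j in seq_along(dt)) {
    xr <- x[risk_idx[[j]]]
    w <- exp(beta * xr)
    s0 <- sum(w); s1 <- sum(w * xr); s2 <- sum(w * xr^2)
    I <- I + d[j] * (s2 / s0 - (s1 / s0)^2)
  }
  se <- if (I > 0) 1 / sqrt(I) else NA_real_
  z <- beta / se
  structure(list(beta = beta, hr = exp(beta), se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 iterations = it, converged = converged, flag = flag,
                 ties = "breslow"),
            class = "cox_result")
}

#' Cox score test statistic at beta = 0
#'
#' U(0)^2 / I(0) of the Breslow partial likelihood; for a binary
#' covariate this equals the log-rank chi-square.
#'
#' @inheritParams cox_univariate
#' @return scalar chi-square statistic (1 df).
#' @export
cox_score_test <- function(x, time, event) {
  dt <- sort(unique(time[event == 1]))
  U <- 0; I <- 0
  for (t in dt) {
    at <- which(time >= t)
    xr <- x[at]
    dj <- sum(time == t & event == 1)
    xbar <- mean(xr)
    U <- U + sum(x[time == t & event == 1]) - dj * xbar
    I <- I + dj * (mean(xr^2) - xbar^2)
  }
  unname(U^2 / I)
}
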