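#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampling from a normal distribution restricted to
#' `[lower, upper]`. A degenerate `sd = 0` returns `mean` repeated (subject
#' to the bounds).
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal; `sd >= 0`.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    x <- rep(min(max(mean, lower), upper), n)
    return(x)
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Density and moments of a truncated normal
#'
#' @param mean,sd Parent normal parameters.
#' @param lower,upper Truncation bounds.
#' @return List with elements `mean` and `sd` of the truncated distribution.
#' @keywords internal
truncnorm_moments <- function(mean, sd, lower, upper) {
  if (sd == 0) return(list(mean = mean, sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  # var = sd^2 * [1 + (a*phi(a)-b*phi(b))/Z - ((phi(a)-phi(b))/Z)^2]
  ta <- if (is.finite(a)) a * da else 0
  tb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (ta - tb) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Moment-match a truncated normal to target mean and sd
#'
#' Solves for parent parameters `(mu, sigma)` such that the normal truncated
#' to `[lower, upper]` has the requested mean and standard deviation. Used so
#' that generated marginals are unbiased with respect to printed summary
#' statistics even when truncation clips a visible tail.
#'
#' @param target_mean,target_sd Moments the truncated distribution must have.
#' @param lower,upper Truncation bounds.
#' @return List with `mean` and `sd` of the parent normal.
#' @export
truncnorm_match <- function(target_mean, target_sd, lower, upper) {
  stopifnot(target_sd >= 0)
  if (target_sd == 0) return(list(mean = target_mean, sd = 0))
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (m$mean - target_mean)^2 / target_sd^2 + (m$sd - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Derive a stage seed from a global seed
#'
#' Deterministic splitting of one global seed into per-stage streams so that
#' adding or re-running one stage does not reshuffle the others. Kept below
#' 2^31 to stay a valid R integer.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @param index Optional integer sub-index (e.g. patient or arm number).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + index * 104729) %% 2147483647)
}

#' Rand index between two partitions
#'
#' Fraction of point pairs on which two clusterings agree (both together or
#' both apart).
#'
#' @param a,b Label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  agree <- sum_comb(tab) +
    (choose(n, 2) - sum_comb(rowSums(tab)) - sum_comb(colSums(tab)) + sum_comb(tab))
  agree / choose(n, 2)
}

# trapezoid integral on an (x, y) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Welch two-sample t-test from summary statistics
#'
#' Unpaired two-tailed t-test when only mean, sd and n of each group are
#' available (e.g. a printed reference column).
#'
#' @param m1,s1,n1 Mean, sd and size of sample 1.
#' @param m2,s2,n2 Mean, sd and size of sample 2.
#' @return List with `statistic`, `df`, `p.value`. If both sds are zero the
#'   test is undefined and `NA` values are returned.
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(statistic = 0, df = NA_real_, p.value = 1))
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}
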