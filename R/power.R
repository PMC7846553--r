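#' Power of the Welch two-sample t-test
#'
#' Analytic power via the noncentral t distribution with
#' Welch-Satterthwaite degrees of freedom, for a mean difference `delta`
#' between groups with SDs `sd1`, `sd2` and sizes `n1`, `n2`.
#'
#' @param n1,n2 group sample sizes.
#' @param sd1,sd2 group standard deviations (> 0).
#' @param delta true difference of means to detect.
#' @param alpha significance level.
#' @param sided `"two"` (default) or `"one"`.
#' @return probability of rejection.
#' @examples
#' t_test_power(42, 71, 1, 1, delta = 0)    # = alpha
#' t_test_power(42, 71, 1, 1, delta = 0.8)
#' @export
t_test_power <- function(n1, n2, sd1, sd2, delta, alpha = 0.05,
                         sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (any(c(sd1, sd2) <= 0)) stop("SDs must be positive")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  ncp <- delta / sqrt(se2)
  if (sided == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Fraction of probes for which a relative mean difference is detectable
#'
#' Batch power computation over a dataset: for each probe, the power of the
#' Welch t-test to detect a difference of `rel_delta` times the reference
#' (group-1) mean, given the probe's own group SDs and the group sizes. The
#' returned coverage is the fraction of probes whose power reaches
#' `power_target`.
#'
#' @param ds an [expression_dataset()].
#' @param rel_delta relative difference of means (e.g. `0.1` for 10%).
#' @param alpha significance level.
#' @param power_target required power.
#' @return list: `coverage` (fraction of probes at or above target),
#'   `power` (per-probe vector).
#' @export
power_coverage <- function(ds, rel_delta = 0.1, alpha = 0.05,
                           power_target = 0.9) {
  st <- probe_group_stats(ds)
  pw <- mapply(function(s1, s2, d) {
    if (s1 <= 0 && s2 <= 0) return(NA_real_)
    t_test_power(st$n1, st$n2, max(sqrt(s1), 1e-12),
                 max(sqrt(s2), 1e-12), d, alpha)
  }, st$v1, st$v2, abs(rel_delta * st$m1))
  list(coverage = mean(pw >= power_target, na.rm = TRUE), power = pw)
}

#' Critical correlation magnitude under the Fisher z approximation
#'
#' Smallest population correlation `rho` such that the Fisher r-to-z test
#' of `H0: rho = 0` at level `alpha` attains the target power at sample
#' size `n`: `rho* = tanh((z_alpha + z_power) / sqrt(n - 3))`. A variant
#' with a `sqrt(n)` denominator is available; the two differ only in the
#' third decimal at these sample sizes.
#'
#' @param n sample size (> 3).
#' @param alpha significance level.
#' @param power target power.
#' @param sided `"one"` (default; reproduces the +/- 0.29 / +/- 0.37
#'   critical values at n = 71 / 42) or `"two"`.
#' @param denom `"n-3"` (standard Fisher variance) or `"n"`.
#' @return critical correlation magnitude in `(0, 1)`.
#' @examples
#' round(correlation_critical_value(71), 2)   # 0.29
#' @export
correlation_critical_value <- function(n, alpha = 0.05, power = 0.8,
                                       sided = c("one", "two"),
                                       denom = c("n-3", "n")) {
  sided <- match.arg(sided); denom <- match.arg(denom)
  if (n <= 3) stop("n must exceed 3")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  za <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  zp <- stats::qnorm(power)
  d <- if (denom == "n-3") sqrt(n - 3) else sqrt(n)
  tanh((za + zp) / d)
}

#' Power of the Fisher z test of zero correlation
#'
#' Companion to [correlation_critical_value()]: the power attained at a true
#' correlation `rho`, so that plugging the critical value back in recovers
#' the target power.
#'
#' @param rho true correlation.
#' @param n sample size (> 3).
#' @inheritParams correlation_critical_value
#' @return probability of rejection.
#' @export
fisher_z_power <- function(rho, n, alpha = 0.05,
                           sided = c("one", "two"),
                           denom = c("n-3", "n")) {
  sided <- match.arg(sided); denom <- match.arg(denom)
  if (n <= 3) stop("n must exceed 3")
  d <- if (denom == "n-3") sqrt(n - 3) else sqrt(n)
  za <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  stats::pnorm(atanh(rho) * d - za)
}

sample_dist <- function(spec, n) {
  if (!is.list(spec) || is.null(spec$dist))
    stop("distribution spec must be list(dist = ..., ...)")
  switch(spec$dist,
         norm = stats::rnorm(n, spec$mean %||% 0, spec$sd %||% 1),
         unif = stats::runif(n, spec$min %||% 0, spec$max %||% 1),
         lnorm = stats::rlnorm(n, spec$meanlog %||% 0, spec$sdlog %||% 1),
         t = stats::rt(n, spec$df %||% 5) + (spec$mean %||% 0),
         stop("unknown distribution: ", spec$dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo power of the Wilcoxon rank-sum test
#'
#' Rejection frequency of the two-sided rank-sum test over `n_sims`
#' simulated two-group datasets; the route used for the rank test whose
#' power has no convenient closed form.
#'
#' @param dist1,dist2 distribution specs, e.g.
#'   `list(dist = "norm", mean = 0, sd = 1)` (also `"unif"`, `"lnorm"`,
#'   `"t"`).
#' @param n1,n2 group sizes.
#' @param alpha significance level.
#' @param n_sims number of simulations (>= 100).
#' @param seed integer seed.
#' @return estimated power with attribute `mc_se` (Monte-Carlo standard
#'   error).
#' @export
wilcoxon_power_sim <- function(dist1, dist2, n1, n2, alpha = 0.05,
                               n_sims = 10000L, seed = 1L) {
  if (n_sims < 100L) stop("n_sims must be >= 100")
  set.seed(as.integer(seed))
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    x <- sample_dist(dist1, n1); y <- sample_dist(dist2, n2)
    rej[i] <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE)$p.value) < alpha
  }
  est <- mean(rej)
  attr(est, "mc_se") <- sqrt(est * (1 - est) / n_sims)
  est
}

#' Shapiro-Wilk normality screen
#'
#' Runs the Shapiro-Wilk test on every probe's series in each group and
#' reports the fraction of series not rejecting normality at `alpha`.
#' Series that are constant or shorter than 3 observations cannot be tested
#' and are counted separately.
#'
#' @param ds an [expression_dataset()].
#' @param alpha significance level.
#' @return list: `pass_fraction` (share of testable series with
#'   `p >= alpha`), `n_tested`, `n_excluded`, `p_values` (matrix probes x 2
#'   groups).
#' @export
normality_screen <- function(ds, alpha = 0.05) {
  x1 <- group_values(ds, 1L); x2 <- group_values(ds, 2L)
  shap <- function(v) {
    if (length(v) < 3L || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  p1 <- apply(x1, 1L, shap)
  p2 <- apply(x2, 1L, shap)
  p <- cbind(group1 = p1, group2 = p2)
  n_exc <- sum(is.na(p))
  if (n_exc > 0L) warning(n_exc, " series excluded (constant or too short)")
  list(pass_fraction = mean(p >= alpha, na.rm = TRUE),
       n_tested = sum(!is.na(p)), n_excluded = n_exc, p_values = p)
}
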