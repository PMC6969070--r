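#' Configuration of the statistical test applied to each study
#'
#' Frequentist studies use a two-tailed one-sample t-test at level `alpha`
#' with population SD 2.0; Bayesian studies use the one-sample
#' Jeffreys-Zellner-Siow Bayes factor with evidence threshold 3 and
#' population SD 1.5 (which yields a "power" of about .8 for a unit effect
#' at n = 34). Sample size defaults to 34 per study.
#'
#' @param framework `"frequentist"` or `"bayesian"`.
#' @param alpha Two-tailed significance level (frequentist).
#' @param sigma Population standard deviation of the observation noise;
#'   defaults to 2.0 (frequentist) or 1.5 (Bayesian).
#' @param n Sample size per study.
#' @param bf_threshold Bayes-factor evidence criterion: BF10 above it is
#'   evidence for an effect, BF10 below its reciprocal evidence for the
#'   null.
#' @param cauchy_scale Scale r of the Cauchy prior on effect size in the
#'   JZS Bayes factor.
#' @return An object of class `test_config`.
#' @export
test_config <- function(framework = c("frequentist", "bayesian"),
                        alpha = 0.05, sigma = NULL, n = 34L,
                        bf_threshold = 3, cauchy_scale = 1) {
  framework <- match.arg(framework)
  if (is.null(sigma)) sigma <- if (framework == "frequentist") 2.0 else 1.5
  stopifnot(alpha > 0, alpha < 1, sigma > 0, n >= 2, bf_threshold > 1,
            cauchy_scale > 0)
  structure(list(framework = framework, alpha = alpha, sigma = sigma,
                 n = as.integer(n), bf_threshold = bf_threshold,
                 cauchy_scale = cauchy_scale, two_tailed = TRUE),
            class = "test_config")
}

#' Stopping rule for the optional-stopping perturbation
#'
#' If a study fails to reach significance with its initial sample, batches
#' of `batch_size` additional participants are added and the full
#' accumulated sample retested, for at most `max_batches` batches or until
#' significance.
#'
#' @param batch_size Participants added per batch (the paper-style
#'   perturbation uses 1, 5 or 10).
#' @param max_batches Maximum number of batches (default 5).
#' @return An object of class `stopping_config`.
#' @export
stopping_config <- function(batch_size, max_batches = 5L) {
  stopifnot(batch_size >= 1, max_batches >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_batches = as.integer(max_batches)),
            class = "stopping_config")
}

#' Draw one study's observations
#'
#' `n` iid draws from Normal(`mu`, `sigma`), where `mu` is the targeted
#' cell's ground truth (0 or 1).
#'
#' @param mu True mean of the targeted cell.
#' @param sigma Population SD (> 0).
#' @param n Sample size (>= 2).
#' @return Numeric vector of observations.
#' @export
draw_sample <- function(mu, sigma, n) {
  stopifnot(n >= 2, sigma > 0)
  stats::rnorm(n, mu, sigma)
}

#' Two-tailed one-sample t-test against zero
#'
#' @param x Numeric observations (>= 2, nonzero variance).
#' @return List with `t_stat`, `p_value`, `df`.
#' @export
one_sample_t <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance sample: t statistic undefined")
  t_stat <- mean(x) / (s / sqrt(n))
  list(t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1)
}

#' Classify a study outcome as notable evidence or not
#'
#' Frequentist: `"sig_effect"` iff p < alpha, else `"inconclusive"`.
#' Bayesian: `"sig_effect"` iff BF10 > threshold, `"sig_null"` iff
#' BF10 < 1/threshold (i.e. BF01 > threshold), else `"inconclusive"`.
#'
#' @param stats A list with `p_value` (frequentist) or `bf10` (Bayesian).
#' @param config A [test_config()].
#' @return One of `"sig_effect"`, `"sig_null"`, `"inconclusive"`.
#' @export
classify_outcome <- function(stats, config) {
  stopifnot(inherits(config, "test_config"))
  if (config$framework == "frequentist") {
    if (stats$p_value < config$alpha) "sig_effect" else "inconclusive"
  } else {
    if (stats$bf10 > config$bf_threshold) "sig_effect"
    else if (stats$bf10 < 1 / config$bf_threshold) "sig_null"
    else "inconclusive"
  }
}

#' Exact power of the two-tailed one-sample t-test
#'
#' Noncentral-t power at standardized effect size `d`: the rejection
#' probability of the two-tailed test at level `alpha` with `n`
#' observations, noncentrality `d * sqrt(n)` and `n - 1` degrees of
#' freedom. At `d = 0` this equals `alpha`.
#'
#' @param d Standardized effect size (mu / sigma).
#' @param alpha Two-tailed significance level.
#' @param n Sample size(s); vectorized.
#' @return Power in \[0, 1\].
#' @export
power_at_n <- function(d, alpha = 0.05, n) {
  stopifnot(all(n >= 2), alpha > 0, alpha < 1)
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Minimum sample size reaching a target power
#'
#' Smallest `n` whose exact two-tailed one-sample noncentral-t power at
#' effect size `d` and level `alpha` reaches `power`. With `d = 0.5` and
#' `alpha = .05` this returns 34 for power .8 and 18 for power .5, the two
#' study sizes used throughout the simulations.
#'
#' @inheritParams power_at_n
#' @param power Target power in (0, 1).
#' @return Integer sample size.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.8) {
  stopifnot(power > 0, power < 1)
  if (d <= 0) stop("power ", power, " unreachable at d = ", d,
                   " (two-tailed rejection rate stays at alpha)")
  # normal-approximation start, then exact scan in both directions
  n <- max(2, ceiling(((stats::qnorm(1 - alpha / 2) +
                          stats::qnorm(power)) / d)^2) - 5)
  while (power_at_n(d, alpha, n) < power) n <- n + 1
  while (n > 2 && power_at_n(d, alpha, n - 1) >= power) n <- n - 1
  as.integer(n)
}

#' Run one simulated study
#'
#' Draws `config$n` observations from Normal(`mu`, `config$sigma`), applies
#' the configured test and classifies the outcome. If a `stopping` rule is
#' supplied and the outcome is not `"sig_effect"`, batches of additional
#' participants are appended and the full accumulated sample retested,
#' until significance or the batch limit.
#'
#' @param mu True mean of the targeted cell (0 or 1).
#' @param config A [test_config()].
#' @param stopping Optional [stopping_config()].
#' @return An object of class `study_outcome`: list with `mu`, `t_stat`,
#'   `p_value`, `df`, `bf10` (Bayesian only, else `NA`), `n_total`,
#'   `evidence`.
#' @export
run_study <- function(mu, config, stopping = NULL) {
  stopifnot(inherits(config, "test_config"))
  x <- draw_sample(mu, config$sigma, config$n)
  out <- .test_and_classify(x, config)
  if (!is.null(stopping)) {
    stopifnot(inherits(stopping, "stopping_config"))
    b <- 0L
    while (out$evidence != "sig_effect" && b < stopping$max_batches) {
      x <- c(x, stats::rnorm(stopping$batch_size, mu, config$sigma))
      out <- .test_and_classify(x, config)
      b <- b + 1L
    }
  }
  structure(list(mu = mu, t_stat = out$t_stat, p_value = out$p_value,
                 df = out$df, bf10 = out$bf10, n_total = length(x),
                 evidence = out$evidence),
            class = "study_outcome")
}

.test_and_classify <- function(x, config) {
  tt <- one_sample_t(x)
  if (config$framework == "bayesian") {
    tt$bf10 <- jzs_bf10(tt$t_stat, length(x), config$cauchy_scale)
  } else {
    tt$bf10 <- NA_real_
  }
  tt$evidence <- classify_outcome(tt, config)
  tt
}
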