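# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# JZS Bayes factor as the Cauchy mixture of noncentral-t densities:
#   BF10 = \int T_nu(t; delta sqrt(n)) Cauchy(delta; 0, r) d delta / T_nu(t; 0)
# (predictive-density ratio), whereas the package integrates the
# Zellner-Siow g-mixture. Agreement between the two routes is a strong
# correctness check because they share no code path.
oracle_jzs_bf10 <- function(t_stat, n, cauchy_scale = 1) {
  nu <- n - 1
  num <- stats::integrate(
    function(delta) suppressWarnings(
      stats::dt(t_stat, nu, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, cauchy_scale),
    -Inf, Inf, rel.tol = 1e-10)$value
  num / stats::dt(t_stat, nu)
}

# Brute-force two-tailed one-sample t rejection rate by direct simulation.
oracle_power_mc <- function(d, alpha, n, n_sim = 50000) {
  x <- matrix(stats::rnorm(n * n_sim, mean = d), nrow = n)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  mean(abs(m / (s / sqrt(n))) > stats::qt(1 - alpha / 2, n - 1))
}

# Long-run probability that a finding is deemed interesting: numerical
# integral of the logistic rule against the generalized Pareto density.
oracle_p_interesting <- function(model) {
  k <- model$shape; s <- model$scale; th <- model$location
  dens <- function(x) (1 / s) * (1 + k * (x - th) / s)^(-1 / k - 1)
  stats::integrate(
    function(x) stats::plogis((x - model$q) / model$temperature) * dens(x),
    th, Inf, rel.tol = 1e-10)$value
}

# Cell overlap between the true and predicted theory windows.
window_overlap <- function(landscape) {
  ws <- landscape$spec$window_size
  a <- landscape$true_anchor
  b <- landscape$predicted_anchor
  ov <- function(x, y) max(0, min(x + ws, y + ws) - max(x, y))
  ov(a[1], b[1]) * ov(a[2], b[2])
}
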