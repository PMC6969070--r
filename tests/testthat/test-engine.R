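# shared small runs reused by several blocks
.disc_cfg <- function(regime, temperature = 1, n_replications = 400,
                      seed = 50, ...) {
  scenario_config(mode = "discovery", regime = regime,
                  interest = interest_model(temperature = temperature),
                  n_replications = n_replications, seed = seed, ...)
}

test_that("scenario_config enforces its structural invariants", {
  expect_error(scenario_config(symmetric_null = TRUE), "Bayesian")
  expect_error(scenario_config(regime = "private",
                               perturb = perturbation("fraud")),
               "public")
  expect_error(perturbation("optional_stopping"), "stopping_config")
  ok <- scenario_config(mode = "theory", test = test_config("bayesian"),
                        symmetric_null = TRUE, rho = 0.5)
  expect_s3_class(ok, "scenario_config")
})

test_that("a first round with no notables costs exactly 100 experiments", {
  cfg <- .disc_cfg("private")
  outcomes <- data.frame(row = 0:4, col = 0:4, truth = 0L,
                         t_stat = 0, p_value = 1, n_total = 34L,
                         evidence = "inconclusive")
  outcomes <- outcomes[rep(1:5, 20), ]
  for (f in list(apply_private_regime, apply_public_regime)) {
    res <- f(outcomes, cfg)
    expect_equal(res$metrics$total_experiments, 100)
    expect_equal(res$metrics$n_replications_run, 0)
    expect_equal(nrow(res$records), 0)
  }
})

test_that("fraud declares every first-round study significant", {
  cfg <- scenario_config(regime = "public",
                         perturb = perturbation("fraud"), seed = 51)
  set.seed(51)
  out <- run_first_round(cfg, generate_discovery_landscape())
  expect_true(all(out$evidence == "sig_effect"))
  expect_equal(nrow(out), 100)
})

test_that("with no true effects notables are a pure type-I process", {
  cfg <- scenario_config(regime = "public", grid = grid_spec(p_h1 = 0),
                         n_replications = 400, seed = 52)
  s <- run_condition(cfg)
  agg <- s$aggregate
  m <- agg$mean[agg$metric == "n_notable_first_round"]
  # Binomial(100, .05): mean 5, per-rep sd ~ 2.18
  expect_lt(abs(m - 5), 3 * sqrt(100 * 0.05 * 0.95 / 400))
  expect_equal(agg$mean[agg$metric == "n_true_interesting"], 0)
})

test_that("experiments are conserved and the public regime never costs more", {
  priv <- run_condition(.disc_cfg("private"))
  pub <- run_condition(.disc_cfg("public"))
  for (s in list(priv, pub)) {
    expect_true(all(s$metrics$total_experiments ==
                      100 + s$metrics$n_replications_run))
    expect_true(all(s$metrics$n_true_interesting <=
                      s$metrics$n_successful_interesting))
    expect_true(all(s$metrics$n_successful_interesting <=
                      s$metrics$n_replications_run))
  }
  # matched seeds: identical first rounds, public replications a subset
  expect_identical(priv$metrics$rep_seed, pub$metrics$rep_seed)
  expect_identical(priv$metrics$n_notable_first_round,
                   pub$metrics$n_notable_first_round)
  expect_true(all(pub$metrics$total_experiments <=
                    priv$metrics$total_experiments))
})

test_that("run_condition is exactly reproducible from its seed", {
  a <- run_condition(.disc_cfg("public", n_replications = 30))
  b <- run_condition(.disc_cfg("public", n_replications = 30))
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$aggregate, b$aggregate)
})

test_that("double type-I errors among private replications occur at rate alpha", {
  cfg <- .disc_cfg("private", seed = 53)
  set.seed(53)
  succ <- 0L; tot <- 0L; int_cor <- NULL
  for (i in 1:600) {
    out <- run_first_round(cfg, generate_discovery_landscape())
    res <- apply_private_regime(out, cfg)
    r <- res$records
    null_notables <- r[r$truth == 0, ]
    succ <- succ + sum(null_notables$replication_success)
    tot <- tot + nrow(null_notables)
    int_cor <- rbind(int_cor, r[, c("truth", "interesting")])
  }
  rate <- succ / tot
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / tot))
  # interest is independent of truth (citations do not predict replicability)
  expect_lt(abs(cor(int_cor$truth, int_cor$interesting)), 0.03)
})

test_that("knowledge parity: the regime does not affect discovery success", {
  # matched seeds give identical first rounds, so the per-replication
  # difference in true interesting discoveries is a paired quantity with
  # expectation zero; pool paired differences across several seeds and
  # test at 3 SE to keep the false-alarm rate of this H0-true check small
  d <- unlist(lapply(c(50, 51, 52, 53), function(seed) {
    priv <- run_condition(.disc_cfg("private", n_replications = 400,
                                    temperature = 5, seed = seed))
    pub <- run_condition(.disc_cfg("public", n_replications = 400,
                                   temperature = 5, seed = seed))
    priv$metrics$n_true_interesting - pub$metrics$n_true_interesting
  }))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("knowledge grows with temperature and with theory quality", {
  know <- function(cfg) {
    a <- run_condition(cfg)$aggregate
    a$mean[a$metric == "n_true_interesting"]
  }
  for (regime in c("private", "public")) {
    ks <- vapply(c(1, 5, 10), function(tmp) {
      know(.disc_cfg(regime, temperature = tmp, n_replications = 300))
    }, numeric(1))
    expect_true(all(diff(ks) >= 0))
  }
  kr <- vapply(c(0.1, 0.5, 1.0), function(rho) {
    know(scenario_config(mode = "theory", regime = "public", rho = rho,
                         interest = interest_model(temperature = 5),
                         n_replications = 300, seed = 54))
  }, numeric(1))
  expect_true(all(diff(kr) >= 0))
})

test_that("p-hacking inflates false interesting replicated effects", {
  base <- run_condition(.disc_cfg("private", temperature = 10,
                                  n_replications = 400, seed = 55))
  hack <- run_condition(.disc_cfg("private", temperature = 10,
                                  n_replications = 400, seed = 55,
                                  perturb = perturbation("p_hack")))
  false_int <- function(s) {
    a <- s$aggregate
    a$mean[a$metric == "n_successful_interesting"] -
      a$mean[a$metric == "n_true_interesting"]
  }
  expect_gt(false_int(hack), false_int(base))
})

test_that("symmetric Bayesian nulls are replicated regardless of interest", {
  cfg <- scenario_config(mode = "theory", regime = "private", rho = 1,
                         test = test_config("bayesian"),
                         symmetric_null = TRUE, seed = 56)
  set.seed(56)
  ls <- place_theory_window(generate_theory_landscape(), 1)
  out <- run_first_round(cfg, ls)
  expect_true(any(out$evidence == "sig_null"))
  res <- apply_private_regime(out, cfg)
  nulls <- res$records[res$records$evidence == "sig_null", ]
  expect_true(all(nulls$replicated))
  expect_true(any(!nulls$interesting))  # replicated even when uninteresting
  # a successful null replication of a truth-0 cell counts as knowledge
  # only when it is also deemed interesting
  expect_true(all(res$records$counted_true ==
                    (res$records$replication_success &
                       res$records$interesting &
                       ((res$records$evidence == "sig_effect" &
                           res$records$truth == 1) |
                          (res$records$evidence == "sig_null" &
                             res$records$truth == 0)))))
})

test_that("optional stopping adds participants but not experiments", {
  cfg <- .disc_cfg("private", n_replications = 50, seed = 57,
                   perturb = perturbation("optional_stopping",
                                          stopping = stopping_config(10)))
  s <- run_condition(cfg)
  base <- run_condition(.disc_cfg("private", n_replications = 50,
                                  seed = 57))
  expect_true(all(s$metrics$total_experiments ==
                    100 + s$metrics$n_replications_run))
  # extra cost is visible in participants, not in the experiment count
  expect_gt(mean(s$metrics$total_participants),
            mean(base$metrics$total_participants))
})

test_that("editorial workload arithmetic holds", {
  expect_equal(editorial_workload(11.75), 188)
  expect_equal(editorial_workload(0), 0)
  expect_equal(editorial_workload(1, editor_multiplier = 1), 8)
})

test_that("aggregate summaries carry Monte-Carlo standard errors", {
  s <- run_condition(.disc_cfg("public", n_replications = 50))
  expect_equal(s$aggregate$se, s$aggregate$sd / sqrt(50))
  expect_true(all(s$aggregate$n == 50))
})
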