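#' Perturbations of the idealized community
#'
#' Questionable-research-practice variants injected into the first round:
#' `p_hack` raises the effective type-I error rate (first-round tests and
#' private-regime replications by the same investigator; community
#' replications in the public regime stay at the nominal alpha);
#' `optional_stopping` adds batches of participants and retests until
#' significance (first-round studies only); `fraud` declares every
#' first-round result significant regardless of the data (public regime
#' only — a fraudulent investigator would fake the private replication
#' too).
#'
#' @param type One of `"none"`, `"p_hack"`, `"optional_stopping"`,
#'   `"fraud"`.
#' @param alpha Inflated alpha for `p_hack` (default 0.2).
#' @param stopping A [stopping_config()] for `optional_stopping`.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(type = c("none", "p_hack", "optional_stopping",
                                  "fraud"),
                         alpha = 0.2, stopping = NULL) {
  type <- match.arg(type)
  if (type == "optional_stopping") {
    if (is.null(stopping)) stop("optional_stopping needs a stopping_config")
    stopifnot(inherits(stopping, "stopping_config"))
  }
  if (type == "p_hack") stopifnot(alpha > 0, alpha < 1)
  structure(list(type = type, alpha = alpha, stopping = stopping),
            class = "perturbation")
}

#' Configuration of one simulated community condition
#'
#' One condition = one cell of the study design: a knowledge-acquisition
#' mode (discovery vs theory-testing with quality `rho`), a statistical
#' framework, an interest model, a replication regime and an optional
#' perturbation. [run_condition()] simulates it for `n_replications`
#' independent communities of `n_first_round` first-round studies each.
#'
#' @param mode `"discovery"` or `"theory"`.
#' @param regime `"private"` (investigators replicate every notable result
#'   before publication) or `"public"` (notable results are published
#'   unreplicated; the community replicates the interesting ones).
#' @param test A [test_config()].
#' @param interest An [interest_model()].
#' @param rho Theory quality in \[0, 1\] (theory mode).
#' @param grid A [grid_spec()]; set `p_h1 = 0` to study a world without
#'   true effects.
#' @param n_first_round Studies in the first round (default 100).
#' @param n_replications Monte-Carlo replications of the whole community
#'   (default 1000).
#' @param symmetric_null If `TRUE` (Bayesian only), convincing evidence for
#'   the null (BF01 > threshold) is also notable: in the private regime
#'   such findings require replication irrespective of interest, and a
#'   successful null replication of a truth-0 cell counts as knowledge.
#' @param perturb A [perturbation()] (default none).
#' @param seed Integer seed; every replication derives its own substream
#'   from it, so any single replication can be re-run in isolation.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("discovery", "theory"),
                            regime = c("private", "public"),
                            test = test_config(),
                            interest = interest_model(),
                            rho = 1, grid = grid_spec(),
                            n_first_round = 100L, n_replications = 1000L,
                            symmetric_null = FALSE,
                            perturb = perturbation("none"),
                            seed = 1L) {
  mode <- match.arg(mode)
  regime <- match.arg(regime)
  stopifnot(inherits(test, "test_config"),
            inherits(interest, "interest_model"),
            inherits(grid, "grid_spec"),
            inherits(perturb, "perturbation"),
            rho >= 0, rho <= 1, n_first_round >= 1, n_replications >= 1)
  if (symmetric_null && test$framework != "bayesian")
    stop("symmetric_null requires the Bayesian framework ",
         "(frequentist tests cannot support the null)")
  if (perturb$type == "fraud" && regime != "public")
    stop("fraud is only simulated under the public regime")
  structure(list(mode = mode, regime = regime, test = test,
                 interest = interest, rho = rho, grid = grid,
                 n_first_round = as.integer(n_first_round),
                 n_replications = as.integer(n_replications),
                 symmetric_null = symmetric_null, perturb = perturb,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# cache of critical |t| values where BF10 crosses the evidence thresholds
.bf_cache <- new.env(parent = emptyenv())

.bf_thresholds <- function(test) {
  key <- paste(test$n, test$bf_threshold, test$cauchy_scale, sep = "_")
  if (is.null(.bf_cache[[key]])) {
    .bf_cache[[key]] <- c(
      hi = bf_critical_t(test$n, test$bf_threshold, test$cauchy_scale),
      lo = bf_critical_t(test$n, 1 / test$bf_threshold, test$cauchy_scale))
  }
  .bf_cache[[key]]
}

# Simulate a batch of studies at true means `mus`, classifying each.
# alpha overrides the config's level (p-hacking); stopping triggers the
# per-study sequential path. Bayesian evidence is classified by comparing
# |t| with the cached critical values where BF10 crosses the evidence
# threshold (equivalent to thresholding BF10, which is strictly increasing
# in |t| at fixed n); bf10 itself is not stored in bulk records.
.simulate_batch <- function(mus, test, alpha = test$alpha, stopping = NULL) {
  k <- length(mus)
  if (k == 0L)
    return(data.frame(t_stat = numeric(0), p_value = numeric(0),
                      n_total = integer(0), evidence = character(0)))
  if (!is.null(stopping)) {
    cfg <- test
    cfg$alpha <- alpha
    outs <- lapply(mus, run_study, config = cfg, stopping = stopping)
    return(data.frame(
      t_stat = vapply(outs, `[[`, numeric(1), "t_stat"),
      p_value = vapply(outs, `[[`, numeric(1), "p_value"),
      n_total = vapply(outs, `[[`, integer(1), "n_total"),
      evidence = vapply(outs, `[[`, character(1), "evidence")))
  }
  n <- test$n
  x <- matrix(stats::rnorm(n * k, mean = rep(mus, each = n),
                           sd = test$sigma), nrow = n)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  t_stat <- m / (s / sqrt(n))
  p_value <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  if (test$framework == "frequentist") {
    evidence <- ifelse(p_value < alpha, "sig_effect", "inconclusive")
  } else {
    crit <- .bf_thresholds(test)
    evidence <- ifelse(abs(t_stat) > crit[["hi"]], "sig_effect",
                ifelse(abs(t_stat) < crit[["lo"]], "sig_null",
                       "inconclusive"))
  }
  data.frame(t_stat = t_stat, p_value = p_value,
             n_total = rep(n, k), evidence = evidence)
}

#' Run the first round of studies for one simulated community
#'
#' Draws `n_first_round` target cells from the landscape (with
#' replacement), simulates each study and classifies its outcome, applying
#' the configured perturbation: `p_hack` tests at the inflated alpha,
#' `optional_stopping` runs the sequential procedure per study, `fraud`
#' relabels every outcome as a significant effect.
#'
#' @param config A [scenario_config()].
#' @param landscape A `landscape` matching `config$mode`.
#' @return A data frame with one row per study: `row`, `col` (0-based
#'   cell), `truth`, `t_stat`, `p_value`, `n_total`, `evidence`.
#' @export
run_first_round <- function(config, landscape) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(landscape, "landscape"),
            landscape$mode == config$mode)
  cells <- sample_target_cell(landscape, config$n_first_round)
  truth <- truth_at(landscape, cells)
  pert <- config$perturb
  alpha <- if (pert$type == "p_hack") pert$alpha else config$test$alpha
  stopping <- if (pert$type == "optional_stopping") pert$stopping else NULL
  out <- .simulate_batch(truth, config$test, alpha = alpha,
                         stopping = stopping)
  if (pert$type == "fraud") out$evidence <- "sig_effect"
  cbind(data.frame(row = cells[, "row"], col = cells[, "col"],
                   truth = truth), out)
}

.is_notable <- function(outcomes, config) {
  outcomes$evidence == "sig_effect" |
    (config$symmetric_null & outcomes$evidence == "sig_null")
}

# knowledge criterion: a successful replication reflects the ground truth
.counted_true <- function(evidence, truth) {
  (evidence == "sig_effect" & truth == 1L) |
    (evidence == "sig_null" & truth == 0L)
}

.empty_records <- function() {
  data.frame(study = integer(0), row = integer(0), col = integer(0),
             truth = integer(0), evidence = character(0),
             citations = numeric(0), p_interest = numeric(0),
             interesting = logical(0), replicated = logical(0),
             rep_evidence = character(0), replication_success = logical(0),
             published = logical(0), counted_true = logical(0))
}

.metrics_row <- function(total_experiments, n_notable, n_published,
                         n_reps, n_succ_int, n_true_int, participants) {
  data.frame(total_experiments = total_experiments,
             n_notable_first_round = n_notable,
             n_published = n_published,
             n_replications_run = n_reps,
             n_successful_interesting = n_succ_int,
             n_true_interesting = n_true_int,
             total_participants = participants)
}

#' Apply the private replication regime to a first round
#'
#' Every notable first-round result is replicated once by its investigator
#' (same cell, same design) before publication; both studies are published
#' only if the replication reaches the same evidence category. The
#' community's interest rule is then applied to the published findings.
#' Cost is the first round plus one replication per notable result. Under
#' `p_hack` the investigator's replications use the inflated alpha; under
#' `symmetric_null`, convincing nulls are replicated irrespective of
#' interest.
#'
#' @param outcomes A first-round data frame from [run_first_round()].
#' @param config A [scenario_config()].
#' @return List with `metrics` (one-row data frame of run metrics) and
#'   `records` (one row per notable finding).
#' @export
apply_private_regime <- function(outcomes, config) {
  idx <- which(.is_notable(outcomes, config))
  part0 <- sum(outcomes$n_total)
  if (length(idx) == 0L)
    return(list(metrics = .metrics_row(config$n_first_round, 0L, 0L, 0L,
                                       0L, 0L, part0),
                records = .empty_records()))
  pert <- config$perturb
  rep_alpha <- if (pert$type == "p_hack") pert$alpha else config$test$alpha
  reps <- .simulate_batch(outcomes$truth[idx], config$test,
                          alpha = rep_alpha)
  success <- reps$evidence == outcomes$evidence[idx]
  published <- success
  int <- draw_interest(config$interest, length(idx))
  interesting <- int$interesting & published
  counted <- interesting &
    .counted_true(outcomes$evidence[idx], outcomes$truth[idx])
  records <- data.frame(
    study = idx, row = outcomes$row[idx], col = outcomes$col[idx],
    truth = outcomes$truth[idx], evidence = outcomes$evidence[idx],
    citations = int$citations, p_interest = int$p_interest,
    interesting = int$interesting, replicated = TRUE,
    rep_evidence = reps$evidence, replication_success = success,
    published = published, counted_true = counted)
  metrics <- .metrics_row(
    total_experiments = config$n_first_round + length(idx),
    n_notable = length(idx),
    n_published = sum(published),
    n_reps = length(idx),
    n_succ_int = sum(interesting),
    n_true_int = sum(counted),
    participants = part0 + sum(reps$n_total))
  list(metrics = metrics, records = records)
}

#' Apply the public replication regime to a first round
#'
#' Every notable first-round result is published without replication. The
#' community then draws interest for each published finding and replicates
#' the interesting ones (at the nominal alpha — community replications are
#' honest even when the first round was perturbed). Cost is the first
#' round plus one replication per interesting finding.
#'
#' @inheritParams apply_private_regime
#' @return List with `metrics` and `records` as in
#'   [apply_private_regime()].
#' @export
apply_public_regime <- function(outcomes, config) {
  idx <- which(.is_notable(outcomes, config))
  part0 <- sum(outcomes$n_total)
  if (length(idx) == 0L)
    return(list(metrics = .metrics_row(config$n_first_round, 0L, 0L, 0L,
                                       0L, 0L, part0),
                records = .empty_records()))
  int <- draw_interest(config$interest, length(idx))
  rep_idx <- which(int$interesting)
  reps <- .simulate_batch(outcomes$truth[idx][rep_idx], config$test)
  success <- logical(length(idx))
  rep_evidence <- rep(NA_character_, length(idx))
  if (length(rep_idx) > 0L) {
    rep_evidence[rep_idx] <- reps$evidence
    success[rep_idx] <- reps$evidence == outcomes$evidence[idx][rep_idx]
  }
  counted <- success &
    .counted_true(outcomes$evidence[idx], outcomes$truth[idx])
  records <- data.frame(
    study = idx, row = outcomes$row[idx], col = outcomes$col[idx],
    truth = outcomes$truth[idx], evidence = outcomes$evidence[idx],
    citations = int$citations, p_interest = int$p_interest,
    interesting = int$interesting, replicated = int$interesting,
    rep_evidence = rep_evidence, replication_success = success,
    published = TRUE, counted_true = counted)
  metrics <- .metrics_row(
    total_experiments = config$n_first_round + length(rep_idx),
    n_notable = length(idx),
    n_published = length(idx),
    n_reps = length(rep_idx),
    n_succ_int = sum(success),
    n_true_int = sum(counted),
    participants = part0 + sum(reps$n_total))
  list(metrics = metrics, records = records)
}

#' Simulate one community condition across Monte-Carlo replications
#'
#' Repeats the full cycle — fresh landscape, first round of studies,
#' replication regime — `n_replications` times and aggregates the run
#' metrics (mean, SD, and Monte-Carlo SE = SD / sqrt(replications)). Each
#' replication runs on its own RNG substream derived from `config$seed`,
#' so results are exactly reproducible and any single replication can be
#' re-run in isolation from its recorded substream seed.
#'
#' @param config A [scenario_config()].
#' @return An object of class `condition_summary`: list with `config`,
#'   `metrics` (one row per replication, including `rep` and `rep_seed`),
#'   and `aggregate` (per-metric mean/sd/se).
#' @export
run_condition <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, config$n_replications,
                          replace = TRUE)
  regime_fn <- if (config$regime == "private") apply_private_regime
               else apply_public_regime
  rows <- vector("list", config$n_replications)
  for (i in seq_len(config$n_replications)) {
    set.seed(rep_seeds[i])
    landscape <- if (config$mode == "discovery") {
      generate_discovery_landscape(config$grid)
    } else {
      place_theory_window(generate_theory_landscape(config$grid),
                          config$rho)
    }
    outcomes <- run_first_round(config, landscape)
    res <- regime_fn(outcomes, config)
    rows[[i]] <- cbind(data.frame(rep = i, rep_seed = rep_seeds[i]),
                       res$metrics)
  }
  metrics <- do.call(rbind, rows)
  structure(list(config = config, metrics = metrics,
                 aggregate = aggregate_metrics(metrics)),
            class = "condition_summary")
}

#' Aggregate per-replication run metrics
#'
#' Mean, SD and Monte-Carlo standard error (SD / sqrt(replications)) for
#' each metric column. Re-aggregating a metrics CSV written by
#' [run_scenario()] reproduces the JSON summary exactly.
#'
#' @param metrics Data frame of per-replication metrics.
#' @return Data frame with columns `metric`, `mean`, `sd`, `se`, `n`.
#' @export
aggregate_metrics <- function(metrics) {
  cols <- setdiff(names(metrics), c("rep", "rep_seed"))
  n <- nrow(metrics)
  data.frame(
    metric = cols,
    mean = vapply(metrics[cols], mean, numeric(1)),
    sd = vapply(metrics[cols], stats::sd, numeric(1)),
    se = vapply(metrics[cols], stats::sd, numeric(1)) / sqrt(n),
    n = n, row.names = NULL)
}

#' Editorial workload implied by a publication count
#'
#' Hours of reviewing and editing implied by an expected number of
#' manuscript submissions: each submission attracts `reviews_per_ms` peer
#' reviews of `hours_per_review` hours, and the `editor_multiplier`
#' accounts for the editor's own time (inviting reviewers, action
#' letters). With the defaults, one manuscript costs 16 h, so the 11.75
#' expected first-round publications of the public regime cost 188 h.
#'
#' @param expected_publications Expected manuscripts.
#' @param reviews_per_ms Average reviews per submission (default 1.6).
#' @param hours_per_review Hours to prepare one review (default 5).
#' @param editor_multiplier Multiplier for editorial overhead (default 2).
#' @return Hours.
#' @export
editorial_workload <- function(expected_publications, reviews_per_ms = 1.6,
                               hours_per_review = 5,
                               editor_multiplier = 2) {
  stopifnot(expected_publications >= 0, reviews_per_ms >= 0,
            hours_per_review >= 0, editor_multiplier >= 0)
  expected_publications * reviews_per_ms * hours_per_review *
    editor_multiplier
}

#' @export
print.condition_summary <- function(x, ...) {
  cfg <- x$config
  cat("<condition_summary>", cfg$mode, "/", cfg$test$framework, "/",
      cfg$regime, "regime |",
      if (cfg$mode == "theory") paste0("rho = ", cfg$rho, " | ") else "",
      "t =", cfg$interest$temperature,
      "|", cfg$n_replications, "replications | seed", cfg$seed, "\n")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-26s %9.3f (sd %8.3f, se %6.3f)\n",
                agg$metric[i], agg$mean[i], agg$sd[i], agg$se[i]))
  invisible(x)
}
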