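#' Catalog of preset simulation scenarios
#'
#' Named presets covering the standard result conditions: discovery mode
#' at both power levels with frequentist inference, Bayesian discovery,
#' frequentist and Bayesian theory-testing across theory qualities, the
#' symmetric Bayesian variant that treats convincing nulls as notable, the
#' p-hacking and optional-stopping perturbations, fraud, a world without
#' true effects, and the interest-threshold percentile sweep. Each preset
#' fully specifies its factor grid (regimes x temperatures x further
#' factors) and a default seed.
#'
#' @return Named list of preset definitions.
#' @export
scenario_catalog <- function() {
  temps <- c(1, 5, 10)
  regimes <- c("private", "public")
  rhos <- c(0.1, 0.5, 1.0)
  list(
    fig4_freq_p8 = list(
      description = "Discovery, frequentist, power .8 (n = 34)",
      mode = "discovery", framework = "frequentist", n = 34L,
      grid = list(regime = regimes, temperature = temps), seed = 101L),
    fig4_freq_p5 = list(
      description = "Discovery, frequentist, power .5 (n = 18)",
      mode = "discovery", framework = "frequentist", n = 18L,
      grid = list(regime = regimes, temperature = temps), seed = 102L),
    fig5_bayes = list(
      description = "Discovery, Bayesian (n = 34, sigma = 1.5, BF > 3)",
      mode = "discovery", framework = "bayesian", n = 34L,
      grid = list(regime = regimes, temperature = temps), seed = 103L),
    fig7_theory_freq = list(
      description = "Theory-testing, frequentist, power .8",
      mode = "theory", framework = "frequentist", n = 34L,
      grid = list(regime = regimes, temperature = temps, rho = rhos),
      seed = 104L),
    fig7_theory_bayes = list(
      description = "Theory-testing, Bayesian",
      mode = "theory", framework = "bayesian", n = 34L,
      grid = list(regime = regimes, temperature = temps, rho = rhos),
      seed = 105L),
    fig8_symmetric = list(
      description = "Theory-testing, symmetric Bayesian (nulls notable)",
      mode = "theory", framework = "bayesian", n = 34L,
      symmetric_null = TRUE,
      grid = list(regime = regimes, temperature = temps, rho = rhos),
      seed = 106L),
    fig9_phack = list(
      description = "Discovery, frequentist, p-hacking (alpha = .2)",
      mode = "discovery", framework = "frequentist", n = 34L,
      perturbation = "p_hack",
      grid = list(regime = regimes, temperature = temps), seed = 107L),
    fig9_stopping = list(
      description = "Discovery, frequentist, optional stopping",
      mode = "discovery", framework = "frequentist", n = 34L,
      perturbation = "optional_stopping",
      grid = list(regime = regimes, temperature = temps,
                  batch_size = c(1L, 5L, 10L)),
      seed = 108L),
    supp_fraud = list(
      description = "Discovery, frequentist, first round fraudulent",
      mode = "discovery", framework = "frequentist", n = 34L,
      perturbation = "fraud",
      grid = list(regime = "public", temperature = temps), seed = 109L),
    supp_no_effects = list(
      description = "Discovery, frequentist, no true effects (P(H1) = 0)",
      mode = "discovery", framework = "frequentist", n = 34L, p_h1 = 0,
      grid = list(regime = regimes, temperature = temps), seed = 110L),
    supp_q_sweep = list(
      description = "Discovery, frequentist, interest-threshold sweep",
      mode = "discovery", framework = "frequentist", n = 34L,
      grid = list(regime = regimes, temperature = temps,
                  threshold_percentile = seq(0.1, 0.9, by = 0.1)),
      seed = 111L)
  )
}

# build a scenario_config for one cell of a preset's factor grid
.build_cell_config <- function(preset, cell, n_replications, seed) {
  tc <- test_config(framework = preset$framework,
                    n = if (is.null(preset$n)) 34L else preset$n)
  im <- interest_model(
    threshold_percentile =
      if (is.null(cell$threshold_percentile)) 0.90
      else cell$threshold_percentile,
    temperature = cell$temperature)
  pert <- if (is.null(preset$perturbation)) {
    perturbation("none")
  } else if (preset$perturbation == "p_hack") {
    perturbation("p_hack", alpha = 0.2)
  } else if (preset$perturbation == "optional_stopping") {
    perturbation("optional_stopping",
                 stopping = stopping_config(cell$batch_size))
  } else {
    perturbation("fraud")
  }
  gs <- grid_spec(p_h1 = if (is.null(preset$p_h1)) 0.09 else preset$p_h1)
  scenario_config(
    mode = preset$mode, regime = cell$regime, test = tc, interest = im,
    rho = if (is.null(cell$rho)) 1 else cell$rho, grid = gs,
    n_replications = n_replications,
    symmetric_null = isTRUE(preset$symmetric_null),
    perturb = pert, seed = seed)
}

# 31-bit polynomial rolling hash over serialized bytes; identifies a
# config in output files (fingerprint only, not cryptographic)
.config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a preset scenario (or a config file) over its factor grid
#'
#' Runs [run_condition()] for every cell of the scenario's factor grid
#' (regimes x temperatures x further factors such as theory quality or
#' batch size), optionally writing one CSV of per-replication metrics and
#' one JSON file of aggregate summaries, both stamped with the seed and a
#' hash of each cell's configuration.
#'
#' @param preset Name of a [scenario_catalog()] entry.
#' @param config_file Path to a JSON scenario file with the same fields as
#'   a preset definition (used when `preset` is `NULL`).
#' @param overrides Named list overriding preset fields (e.g.
#'   `list(n = 18)`), applied before the grid is expanded.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing.
#' @param n_replications Monte-Carlo replications per cell (default 1000).
#' @param seed Base seed; cell `i` runs at `seed + i - 1`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cells` (the expanded factor grid),
#'   `summaries` (one `condition_summary` per cell), `metrics` (combined
#'   per-replication data frame) and `aggregate` (combined summary data
#'   frame).
#' @export
run_scenario <- function(preset = NULL, config_file = NULL,
                         overrides = list(), out_dir = NULL,
                         n_replications = 1000L, seed = NULL,
                         quiet = FALSE) {
  if (!is.null(preset)) {
    catalog <- scenario_catalog()
    if (!preset %in% names(catalog))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(catalog), collapse = ", "))
    def <- catalog[[preset]]
    name <- preset
  } else if (!is.null(config_file)) {
    def <- jsonlite::fromJSON(config_file, simplifyVector = TRUE)
    def$grid <- as.list(def$grid)
    name <- tools::file_path_sans_ext(basename(config_file))
  } else {
    stop("supply a preset name or a config file")
  }
  bad <- setdiff(names(overrides), c(names(def), "p_h1", "perturbation"))
  if (length(bad) > 0)
    stop("invalid override key(s): ", paste(bad, collapse = ", "))
  def[names(overrides)] <- overrides
  if (is.null(seed)) seed <- def$seed
  cells <- expand.grid(def$grid, stringsAsFactors = FALSE)
  summaries <- vector("list", nrow(cells))
  metrics_list <- vector("list", nrow(cells))
  agg_list <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, , drop = FALSE])
    cfg <- .build_cell_config(def, cell, n_replications, seed + i - 1L)
    if (!quiet)
      message(sprintf("[%s] cell %d/%d (%s) seed %d", name, i,
                      nrow(cells),
                      paste(names(cell), unlist(cell), sep = "=",
                            collapse = ", "),
                      cfg$seed))
    summaries[[i]] <- run_condition(cfg)
    id_cols <- cbind(data.frame(cell = i), cells[i, , drop = FALSE],
                     row.names = NULL)
    metrics_list[[i]] <- cbind(id_cols, summaries[[i]]$metrics,
                               row.names = NULL)
    agg <- summaries[[i]]$aggregate
    agg_list[[i]] <- cbind(id_cols[rep(1, nrow(agg)), , drop = FALSE],
                           agg, row.names = NULL)
  }
  metrics <- do.call(rbind, metrics_list)
  aggregate <- do.call(rbind, agg_list)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics,
                     file.path(out_dir, paste0(name, "_metrics.csv")),
                     row.names = FALSE)
    doc <- list(
      scenario = name, base_seed = seed,
      n_replications = n_replications,
      cells = lapply(seq_len(nrow(cells)), function(i) {
        list(cell = i, factors = as.list(cells[i, , drop = FALSE]),
             seed = summaries[[i]]$config$seed,
             config_hash = .config_hash(summaries[[i]]$config),
             aggregate = summaries[[i]]$aggregate)
      }))
    jsonlite::write_json(doc,
                         file.path(out_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!quiet)
      message("wrote ", name, "_metrics.csv and ", name,
              "_summary.json to ", out_dir)
  }
  invisible(list(cells = cells, summaries = summaries, metrics = metrics,
                 aggregate = aggregate))
}
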