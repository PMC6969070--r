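#' Specification of an effect landscape
#'
#' A landscape is a grid of cells, each representing a unique combination of
#' an experimental manipulation (row) and an outcome measure (column). The
#' ground truth in a cell is 1 (a real effect of unit size) or 0 (no effect).
#' Each cell is a true effect with probability `p_h1`, reflecting the
#' estimated base rate of a psychological hypothesis being true.
#'
#' @param n_rows,n_cols Grid dimensions (default 10 x 10).
#' @param window_size Side length of the square cluster window used in
#'   theory-testing mode (default 4).
#' @param p_h1 Probability that a cell holds a true effect (default 0.09).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 10, n_cols = 10, window_size = 4, p_h1 = 0.09) {
  stopifnot(n_rows >= 1, n_cols >= 1,
            window_size >= 1, window_size <= min(n_rows, n_cols),
            p_h1 >= 0, p_h1 <= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 window_size = as.integer(window_size), p_h1 = p_h1),
            class = "grid_spec")
}

new_landscape <- function(truth, mode, spec,
                          true_anchor = NULL, predicted_anchor = NULL) {
  structure(list(truth = truth, mode = mode, spec = spec,
                 true_anchor = true_anchor,
                 predicted_anchor = predicted_anchor),
            class = "landscape")
}

#' Generate a discovery-oriented effect landscape
#'
#' Each cell is independently set to 1 with probability `p_h1`. No spatial
#' structure is imposed; this models discovery-oriented research foraging
#' across an unstructured search space. Uses the current R random stream:
#' call [set.seed()] for reproducibility.
#'
#' @param spec A [grid_spec()].
#' @return A `landscape` object with `mode = "discovery"` and no anchors.
#' @export
generate_discovery_landscape <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  truth <- matrix(stats::rbinom(spec$n_rows * spec$n_cols, 1L, spec$p_h1),
                  nrow = spec$n_rows, ncol = spec$n_cols)
  new_landscape(truth, "discovery", spec)
}

#' Generate a theory-testing effect landscape
#'
#' All true effects are clustered inside a `window_size` x `window_size`
#' window placed uniformly at random among positions where it fits entirely
#' inside the grid. The number of effects is drawn as
#' Binomial(`n_rows * n_cols`, `p_h1`) so that the marginal effect rate
#' matches discovery mode, then capped at the window capacity (with a
#' message if the cap binds); that many distinct cells inside the window are
#' chosen uniformly and set to 1.
#'
#' Anchors are 0-based (row, col) coordinates of the window's top-left cell,
#' so for a 10 x 10 grid with a 4 x 4 window the feasible anchor set is
#' rows/cols 0..6.
#'
#' @param spec A [grid_spec()].
#' @return A `landscape` with `mode = "theory"` and `true_anchor` set;
#'   `predicted_anchor` is unset until [place_theory_window()] is called.
#' @export
generate_theory_landscape <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  ws <- spec$window_size
  anchor <- c(sample.int(spec$n_rows - ws + 1L, 1L) - 1L,
              sample.int(spec$n_cols - ws + 1L, 1L) - 1L)
  capacity <- ws * ws
  n_eff <- stats::rbinom(1L, spec$n_rows * spec$n_cols, spec$p_h1)
  if (n_eff > capacity) {
    message("effect count ", n_eff, " exceeds window capacity ", capacity,
            "; capping")
    n_eff <- capacity
  }
  truth <- matrix(0L, nrow = spec$n_rows, ncol = spec$n_cols)
  if (n_eff > 0L) {
    idx <- sample.int(capacity, n_eff) - 1L
    rows <- anchor[1L] + idx %/% ws
    cols <- anchor[2L] + idx %% ws
    truth[cbind(rows + 1L, cols + 1L)] <- 1L
  }
  new_landscape(truth, "theory", spec, true_anchor = anchor)
}

# round half away from zero, unlike round()'s banker's rounding
round_half_out <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Place the theory's predicted search window
#'
#' Theory quality `rho` in \[0, 1\] controls the proximity of the predicted
#' window to the true-effect cluster: the predicted centroid is displaced
#' `(1 - rho) * (dim - 1)` rows and columns from the true centroid (4.5
#' rounds to 5), in a direction chosen uniformly per dimension among
#' directions that yield any displacement, then clipped so the window fits
#' inside the grid. With `rho = 1` the windows coincide; with `rho` near 0
#' the theory searches where no effects exist.
#'
#' @param landscape A theory-mode `landscape` with `true_anchor` set.
#' @param rho Theory quality in \[0, 1\].
#' @return The landscape with `predicted_anchor` set.
#' @export
place_theory_window <- function(landscape, rho) {
  stopifnot(inherits(landscape, "landscape"),
            landscape$mode == "theory", !is.null(landscape$true_anchor),
            rho >= 0, rho <= 1)
  spec <- landscape$spec
  ws <- spec$window_size
  amax <- c(spec$n_rows - ws, spec$n_cols - ws)
  dims <- c(spec$n_rows, spec$n_cols)
  anchor <- integer(2L)
  for (d in 1:2) {
    a <- landscape$true_anchor[d]
    delta <- round_half_out((1 - rho) * (dims[d] - 1L))
    cand <- unique(pmin(pmax(a + c(delta, -delta), 0L), amax[d]))
    cand <- cand[cand != a]
    anchor[d] <- as.integer(
      if (length(cand) == 0L) a
      else if (length(cand) == 1L) cand
      else cand[sample.int(2L, 1L)])
  }
  landscape$predicted_anchor <- anchor
  landscape
}

#' Sample target cells for experiments
#'
#' Discovery mode draws a cell uniformly over the whole grid (sampling with
#' replacement across calls, so the same effect can be discovered more than
#' once). Theory mode draws uniformly over the cells of the predicted
#' window, which must have been placed with [place_theory_window()].
#'
#' @param landscape A `landscape`.
#' @param k Number of cells to draw.
#' @return An integer matrix with `k` rows and columns `row`, `col`
#'   (0-based coordinates).
#' @export
sample_target_cell <- function(landscape, k = 1L) {
  stopifnot(inherits(landscape, "landscape"), k >= 1)
  spec <- landscape$spec
  if (landscape$mode == "discovery") {
    rows <- sample.int(spec$n_rows, k, replace = TRUE) - 1L
    cols <- sample.int(spec$n_cols, k, replace = TRUE) - 1L
  } else {
    if (is.null(landscape$predicted_anchor))
      stop("theory-mode landscape has no predicted window; ",
           "call place_theory_window() first")
    ws <- spec$window_size
    rows <- landscape$predicted_anchor[1L] + sample.int(ws, k, replace = TRUE) - 1L
    cols <- landscape$predicted_anchor[2L] + sample.int(ws, k, replace = TRUE) - 1L
  }
  cbind(row = rows, col = cols)
}

#' Look up ground truth at 0-based cell coordinates
#'
#' @param landscape A `landscape`.
#' @param cells Integer matrix with columns `row`, `col` (0-based).
#' @return Integer vector of 0/1 truth values.
#' @export
truth_at <- function(landscape, cells) {
  landscape$truth[cbind(cells[, 1L] + 1L, cells[, 2L] + 1L)]
}

#' Serialize and restore landscapes as JSON
#'
#' The JSON document stores the truth grid as nested row-major arrays, the
#' mode, the 0-based anchors (when present) and the generating spec, so that
#' a landscape can be frozen as a plain-text fixture and reloaded exactly.
#'
#' @param landscape A `landscape`.
#' @param path File path; `landscape_to_json` returns the JSON string
#'   invisibly and writes to `path` when given.
#' @return `landscape_to_json`: JSON string. `landscape_from_json`: a
#'   `landscape`.
#' @export
landscape_to_json <- function(landscape, path = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  doc <- list(
    mode = landscape$mode,
    truth = apply(landscape$truth, 1L, identity, simplify = FALSE),
    true_anchor = landscape$true_anchor,
    predicted_anchor = landscape$predicted_anchor,
    spec = unclass(landscape$spec)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) writeLines(json, path)
  invisible(json)
}

#' @rdname landscape_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
landscape_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyMatrix = FALSE)
  spec <- do.call(grid_spec, doc$spec)
  truth <- do.call(rbind, lapply(doc$truth, as.integer))
  anc <- function(x) if (is.null(x)) NULL else as.integer(x)
  new_landscape(truth, doc$mode, spec,
                true_anchor = anc(doc$true_anchor),
                predicted_anchor = anc(doc$predicted_anchor))
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> mode:", x$mode,
      "| grid:", x$spec$n_rows, "x", x$spec$n_cols,
      "| true effects:", sum(x$truth), "\n")
  if (!is.null(x$true_anchor))
    cat("  true window anchor (0-based): (",
        x$true_anchor[1], ",", x$true_anchor[2], ")\n")
  if (!is.null(x$predicted_anchor))
    cat("  predicted window anchor (0-based): (",
        x$predicted_anchor[1], ",", x$predicted_anchor[2], ")\n")
  invisible(x)
}
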