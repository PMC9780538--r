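#' Discrete awareness grid
#'
#' The awareness state lives on the open unit interval, discretised with a
#' fixed step. With the default step of 0.01 the levels are
#' \{0.01, 0.02, ..., 0.99\}: the interval endpoints 0 and 1 are excluded, so
#' awareness is never total nor entirely absent.
#'
#' @param step Awareness increment per shock (dimensionless, default 0.01).
#'   Must divide the unit interval into at least three interior levels.
#' @return An object of class `aware_grid`: a list with `levels` (ordered
#'   awareness values), `step`, `n`, `lower_bound` and `upper_bound`.
#' @examples
#' g <- state_grid()
#' range(g$levels)
#' @export
state_grid <- function(step = 0.01) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step >= 0.5) {
    abort("`step` must be a single number in (0, 0.5).")
  }
  n <- round(1 / step) - 1L
  if (abs(1 / step - round(1 / step)) > 1e-8) {
    abort("`step` must divide 1 evenly (e.g. 0.01, 0.02, 0.05).")
  }
  levels <- seq_len(n) * step
  structure(
    list(
      step = step,
      n = n,
      levels = levels,
      lower_bound = levels[1L],
      upper_bound = levels[n]
    ),
    class = "aware_grid"
  )
}

#' @export
print.aware_grid <- function(x, ...) {
  cat(sprintf(
    "<aware_grid> %d levels in [%.3g, %.3g], step %.3g\n",
    x$n, x$lower_bound, x$upper_bound, x$step
  ))
  invisible(x)
}

#' Snap a value to the nearest grid level
#'
#' Off-grid values are snapped to the nearest level with a warning; values
#' outside the grid range are clamped to the boundary levels.
#'
#' @param s Numeric vector of awareness values.
#' @param grid An [state_grid()] object.
#' @param warn Emit a warning when snapping moves a value (default `TRUE`).
#' @return Indices into `grid$levels` (integer vector).
#' @export
snap_to_grid <- function(s, grid = state_grid(), warn = TRUE) {
  idx <- pmin(pmax(round(s / grid$step), 1L), grid$n)
  off <- abs(grid$levels[idx] - s) > 1e-9
  if (warn && any(off)) {
    warn(sprintf(
      "%d value(s) were off-grid and snapped to the nearest level.",
      sum(off)
    ))
  }
  as.integer(idx)
}

#' Apply a shock to an awareness level
#'
#' Moves the state by `shock` grid steps, clamping at the grid boundaries:
#' an impossible move at the boundary leaves the state unchanged, so the
#' realised dynamics never leave the grid.
#'
#' @param s Awareness level(s) on the grid.
#' @param shock Integer shock(s) in \{-1, 0, +1\}.
#' @inheritParams snap_to_grid
#' @return Awareness level(s) after the clamped move.
#' @examples
#' step_state(0.20, +1)
#' step_state(0.99, +1) # clamped at the upper bound
#' @export
step_state <- function(s, shock, grid = state_grid()) {
  if (!all(shock %in% c(-1L, 0L, 1L))) {
    abort("`shock` must be -1, 0 or +1.")
  }
  idx <- snap_to_grid(s, grid)
  idx2 <- pmin(pmax(idx + as.integer(shock), 1L), grid$n)
  grid$levels[idx2]
}
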