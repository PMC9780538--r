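#' Shape of the forward-transition probability curves
#'
#' The probability that a decision raises the awareness state follows a
#' unimodal "beta bump" in the decision `u`:
#' `p(u) = p_floor + (p_peak - p_floor) * u^a (1-u)^b / max_u[u^a (1-u)^b]`.
#' The exponents are parameterised through the location of the peak and a
#' concentration: `a = concentration * peak`, `b = concentration * (1 - peak)`,
#' which places the maximiser exactly at `peak`. The analytical curve peaks at
#' a high decision value and then declines (excessive analyticity overfits the
#' available information); the intuitive curve mirrors it, peaking at a low
#' decision value and dropping towards the floor as `u` approaches 0 (a
#' minimum of analyticity is indispensable) and 1.
#'
#' The defaults (peaks 0.8/0.2, concentration 2.5, floor 0.05, peak
#' probability 0.9) are the package's calibration of the curve family; see the
#' methods vignette for how they were chosen.
#'
#' @param p_floor Minimum forward probability, approached at both ends of the
#'   decision interval (default 0.05).
#' @param p_peak Maximum forward probability, attained at the curve's peak
#'   (default 0.9). Must satisfy `p_peak + p_stay <= 1`.
#' @param peak_analytical Decision value at which the analytical curve peaks
#'   (default 0.8).
#' @param peak_intuitive Decision value at which the intuitive curve peaks
#'   (default 0.2).
#' @param concentration Sharpness of the bumps; the exponent pair is
#'   `concentration * c(peak, 1 - peak)` (default 2.5, giving exponents
#'   (2, 0.5) for the default analytical peak).
#' @param p_stay Stationary probability, constant in `u` (default 0.1). It
#'   models the decision-maker's inertia against changing awareness.
#' @return An object of class `aware_curve_shape`.
#' @examples
#' sh <- curve_shape()
#' base_forward_analytical(0.8, sh) # the peak
#' @export
curve_shape <- function(p_floor = 0.05, p_peak = 0.9,
                        peak_analytical = 0.8, peak_intuitive = 0.2,
                        concentration = 2.5, p_stay = 0.1) {
  problems <- character()
  if (!(p_floor >= 0 && p_floor < p_peak)) {
    problems <- c(problems, "need 0 <= p_floor < p_peak")
  }
  if (p_peak + p_stay > 1 + 1e-12) {
    problems <- c(problems,
      "p_peak + p_stay must not exceed 1 (probability budget)")
  }
  if (!(peak_intuitive > 0 && peak_intuitive < peak_analytical &&
        peak_analytical < 1)) {
    problems <- c(problems, "need 0 < peak_intuitive < peak_analytical < 1")
  }
  if (concentration <= 0) problems <- c(problems, "concentration must be > 0")
  if (p_stay < 0 || p_stay > 1) problems <- c(problems, "p_stay must be in [0, 1]")
  if (length(problems)) {
    abort(paste0("Invalid curve shape:\n", paste("-", problems, collapse = "\n")))
  }
  structure(
    list(
      p_floor = p_floor, p_peak = p_peak,
      peak_analytical = peak_analytical, peak_intuitive = peak_intuitive,
      concentration = concentration, p_stay = p_stay
    ),
    class = "aware_curve_shape"
  )
}

#' @export
print.aware_curve_shape <- function(x, ...) {
  cat(sprintf(
    paste0("<aware_curve_shape> floor %.3g, peak %.3g at u = %.2f (analytical)",
           " / %.2f (intuitive), concentration %.3g, stay %.3g\n"),
    x$p_floor, x$p_peak, x$peak_analytical, x$peak_intuitive,
    x$concentration, x$p_stay
  ))
  invisible(x)
}

# normalized beta bump with maximum 1 at `peak`
beta_bump <- function(u, peak, concentration) {
  a <- concentration * peak
  b <- concentration * (1 - peak)
  exp(a * (log(u) - log(peak)) + b * (log1p(-u) - log1p(-peak)))
}

check_u <- function(u) {
  if (any(u <= 0 | u >= 1)) abort("decisions `u` must lie in the open interval (0, 1).")
  invisible(u)
}

#' Base forward probabilities for the two reasoning styles
#'
#' `base_forward_analytical()` is low for intuitive decisions, rises to
#' `p_peak` at `peak_analytical` and declines again for near-total
#' analyticity. `base_forward_intuitive()` is its mirror image, peaking at
#' `peak_intuitive` and declining as the decision becomes more analytical.
#'
#' @param u Decision value(s) in (0, 1); vectorised.
#' @param shape A [curve_shape()] object.
#' @return Forward probability value(s).
#' @examples
#' base_forward_intuitive(0.2) # equals p_peak at the intuitive peak
#' @export
base_forward_analytical <- function(u, shape = curve_shape()) {
  check_u(u)
  shape$p_floor + (shape$p_peak - shape$p_floor) *
    beta_bump(u, shape$peak_analytical, shape$concentration)
}

#' @rdname base_forward_analytical
#' @export
base_forward_intuitive <- function(u, shape = curve_shape()) {
  check_u(u)
  shape$p_floor + (shape$p_peak - shape$p_floor) *
    beta_bump(u, shape$peak_intuitive, shape$concentration)
}

#' Mixed forward-transition probability
#'
#' The effective forward probability of an individual is the convex
#' combination of the analytical and intuitive base curves weighted by the
#' reasoning propensity: `P1(u) = p_r * P1_analytical(u) + (1 - p_r) *
#' P1_intuitive(u)`.
#'
#' @inheritParams base_forward_analytical
#' @param p_r Reasoning propensity in \[0, 1\] (0 = fully intuitive,
#'   1 = fully analytical).
#' @return Forward probability value(s).
#' @export
forward_prob <- function(u, p_r, shape = curve_shape()) {
  if (any(p_r < 0 | p_r > 1)) abort("`p_r` must lie in [0, 1].")
  p_r * base_forward_analytical(u, shape) +
    (1 - p_r) * base_forward_intuitive(u, shape)
}

#' Transition probabilities of one decision
#'
#' Assembles the row-stochastic triple (up, stay, down) for a decision:
#' the forward probability from [forward_prob()], the constant stationary
#' probability, and the backward probability as the residual
#' `1 - (P1 + P0)`.
#'
#' @inheritParams forward_prob
#' @return A tibble with columns `u`, `p_up`, `p_stay`, `p_down` (one row per
#'   decision value).
#' @examples
#' transition_row(0.5, p_r = 0.5)
#' @export
transition_row <- function(u, p_r, shape = curve_shape()) {
  p_up <- forward_prob(u, p_r, shape)
  p_down <- 1 - p_up - shape$p_stay
  if (any(p_down < -1e-12)) {
    abort(paste0(
      "Curve shape violates the probability budget: ",
      "forward + stationary probability exceeds 1 for some decisions."
    ))
  }
  tibble::tibble(
    u = u, p_up = p_up, p_stay = shape$p_stay, p_down = pmax(p_down, 0)
  )
}

# action-indexed kernel as a plain matrix (rows = actions on `u_levels`)
transition_matrix <- function(u_levels, p_r, shape) {
  row <- transition_row(u_levels, p_r, shape)
  cbind(up = row$p_up, stay = row$p_stay, down = row$p_down)
}

#' Sample a state shock
#'
#' Draws shocks in \{+1, 0, -1\} with the probabilities of a transition row,
#' using R's current random stream (seed it with `set.seed()` for
#' reproducibility).
#'
#' @param row A one-row data frame with `p_up`, `p_stay`, `p_down` (as
#'   returned by [transition_row()]), or a numeric triple.
#' @param n Number of shocks to draw.
#' @return Integer vector of shocks.
#' @export
sample_shock <- function(row, n = 1) {
  p <- if (is.data.frame(row)) c(row$p_up[1], row$p_stay[1], row$p_down[1]) else row[1:3]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`row` must be a non-negative probability triple summing to 1.")
  }
  r <- runif(n)
  ifelse(r < p[1], 1L, ifelse(r < p[1] + p[2], 0L, -1L))
}

#' Kernel diagnostic curves over the decision grid
#'
#' Tabulates the up/stay/down probabilities over the whole decision grid for
#' one or more reasoning propensities, for visual inspection of the kernel.
#'
#' @inheritParams forward_prob
#' @param p_r Vector of reasoning propensities.
#' @param grid State grid whose levels double as the decision grid.
#' @return A long tibble with columns `p_r`, `u`, `p_up`, `p_stay`, `p_down`.
#' @export
transition_curves <- function(p_r = c(0, 0.5, 1), shape = curve_shape(),
                              grid = state_grid()) {
  purrr::map_dfr(p_r, function(pr) {
    dplyr::mutate(transition_row(grid$levels, pr, shape), p_r = pr, .before = 1)
  })
}
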