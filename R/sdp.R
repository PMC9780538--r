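#' Habitual decisions
#'
#' The habitual (unaware) policy ignores state and epoch entirely: every
#' decision is a Gaussian draw around the individual's reasoning propensity,
#' clipped to the decision grid range and snapped to the grid. Uses R's
#' current random stream.
#'
#' @param n Number of decisions to draw.
#' @param p_r Reasoning propensity (mean of the draws).
#' @param sigma Decision noise standard deviation; `sigma = 0` always returns
#'   `p_r` snapped to the grid.
#' @param grid An [state_grid()] object (the decision grid).
#' @return Numeric vector of decisions on the grid.
#' @examples
#' set.seed(1)
#' habitual_action(5, p_r = 0.6, sigma = 0.08)
#' @export
habitual_action <- function(n = 1, p_r, sigma, grid = state_grid()) {
  e <- rnorm(n, mean = p_r, sd = sigma)
  idx <- pmin(pmax(round(e / grid$step), 1L), grid$n)
  grid$levels[idx]
}

# exact action-weight vector of the habitual policy on the decision grid:
# P(snap(clip(e)) = u_k) for e ~ N(p_r, sigma), clip to grid range, snap
habitual_action_weights <- function(p_r, sigma, grid = state_grid()) {
  n <- grid$n
  if (sigma == 0) {
    w <- numeric(n)
    w[pmin(pmax(round(p_r / grid$step), 1L), n)] <- 1
    return(w)
  }
  half <- grid$step / 2
  upper <- c(grid$levels[-n] + half, Inf)
  lower <- c(-Inf, grid$levels[-1] - half)
  pnorm(upper, p_r, sigma) - pnorm(lower, p_r, sigma)
}

# --- internal solver core -------------------------------------------------
#
# An "instance" is the minimal structure the backward-induction machinery
# needs; both full configurations and hand-built tiny instances reduce to it:
#   n_s, n_t          state count, horizon
#   u                 action values (for cost-free instances may be NA)
#   P                 n_a x 3 kernel (up / stay / down), rows sum to 1
#   reward            n_s x n_a stage-reward matrix
#   terminal          length-n_s terminal reward
#   gamma             direction weights (up, stay, down)
#   discount          function(tau) -> length-n_s vector of future weights

as_instance <- function(config) {
  grid <- config$grid
  u <- grid$levels
  P <- transition_matrix(u, config$p_r, config$shape)
  reward <- outer(config$rewards$alpha * grid$levels, config$rewards$beta * u, `-`)
  term <- terminal_reward(grid$levels, config$rewards)
  emo <- config$emotion
  rew <- config$rewards
  T_h <- config$T_horizon
  discount <- if (emo$enabled) {
    ds <- emotion_delta(grid$levels, emo)
    function(tau) ds * (tau / T_h)
  } else {
    d <- rep(rew$delta, grid$n)
    function(tau) d
  }
  list(n_s = grid$n, n_t = T_h, u = u, P = P, reward = reward,
       terminal = term, gamma = rew$gamma, discount = discount)
}

# gamma-weighted backup of a value slice for every (state, action) pair;
# boundary moves use the clamped neighbour's value
backup_matrix <- function(v_next, inst, tau) {
  n_s <- inst$n_s
  up <- pmin(seq_len(n_s) + 1L, n_s)
  dn <- pmax(seq_len(n_s) - 1L, 1L)
  g <- inst$gamma
  W <- g[1] * outer(v_next[up], inst$P[, 1]) +
       g[2] * outer(v_next, inst$P[, 2]) +
       g[3] * outer(v_next[dn], inst$P[, 3])
  inst$reward + inst$discount(tau) * W
}

solve_instance <- function(inst) {
  n_s <- inst$n_s; n_t <- inst$n_t
  V <- matrix(0, n_s, n_t + 1L)
  pol <- matrix(NA_integer_, n_s, n_t)
  V[, n_t + 1L] <- inst$terminal
  for (tau in seq(n_t - 1L, 0L)) {
    Q <- backup_matrix(V[, tau + 2L], inst, tau)
    a <- max.col(Q, ties.method = "first") # ties broken toward smallest u
    pol[, tau + 1L] <- a
    V[, tau + 1L] <- Q[cbind(seq_len(n_s), a)]
  }
  list(policy_idx = pol, values = V)
}

# evaluate a fixed policy (n_s x n_t action-index matrix) under the same
# backup semantics as the solver
evaluate_policy_instance <- function(inst, policy_idx) {
  n_s <- inst$n_s; n_t <- inst$n_t
  V <- matrix(0, n_s, n_t + 1L)
  V[, n_t + 1L] <- inst$terminal
  for (tau in seq(n_t - 1L, 0L)) {
    Q <- backup_matrix(V[, tau + 2L], inst, tau)
    V[, tau + 1L] <- Q[cbind(seq_len(n_s), policy_idx[, tau + 1L])]
  }
  V
}

#' Single Bellman backup value
#'
#' The value of taking decision `u` in state `s` at stage `tau` when the next
#' stage is worth `v_next`: the stage reward plus the discounted,
#' direction-weighted combination of the clamped neighbours' values,
#' `r(s, u) + D * (g1 * v(s+) * p_up + g2 * v(s) * p_stay + g3 * v(s-) *
#' p_down)`, where `D` is the [effective_discount()] at `(s, tau)`.
#'
#' This scalar form exists for transparency and testing; [solve_sdp()] uses a
#' vectorised equivalent.
#'
#' @param s Awareness level on the grid.
#' @param u Decision value on the grid.
#' @param v_next Value slice at stage `tau + 1` over the full grid.
#' @param tau Stage index in `0:(T-1)`.
#' @param config An [aware_config()] object.
#' @return The backup value (scalar).
#' @export
bellman_backup <- function(s, u, v_next, tau, config) {
  grid <- config$grid
  if (length(v_next) != grid$n) {
    abort("`v_next` must cover the full state grid.")
  }
  i <- snap_to_grid(s, grid)
  row <- transition_row(u, config$p_r, config$shape)
  D <- effective_discount(grid$levels[i], tau, config$T_horizon,
                          config$rewards, config$emotion)
  g <- config$rewards$gamma
  up <- min(i + 1L, grid$n); dn <- max(i - 1L, 1L)
  stage_reward(grid$levels[i], u, config$rewards) +
    D * (g[1] * v_next[up] * row$p_up +
         g[2] * v_next[i] * row$p_stay +
         g[3] * v_next[dn] * row$p_down)
}

#' Solve for the self-aware (optimal) policy by backward induction
#'
#' Computes the optimal decision for every (state, epoch) pair by stochastic
#' dynamic programming: starting from the terminal reward at the horizon, each
#' stage maximises the [bellman_backup()] over the decision grid, ties broken
#' toward the smallest (cheapest) decision. The computation is deterministic:
#' no randomness is involved.
#'
#' @param config An [aware_config()] object.
#' @return An object of class `aware_sdp` with elements `policy` (levels
#'   matrix, states x epochs), `policy_idx`, `values` (states x epochs+1,
#'   the last column equal to the terminal reward), `config` and
#'   `config_hash`.
#' @examples
#' fit <- solve_sdp(aware_config(p_r = 0.6, sigma = 0.08, s0 = 0.2,
#'                               T_horizon = 20, N = 1))
#' tidy(fit)
#' @export
solve_sdp <- function(config) {
  stopifnot(inherits(config, "aware_config"))
  if (config$grid$n < 1L) abort("empty decision grid.")
  inst <- as_instance(config)
  sol <- solve_instance(inst)
  structure(
    list(
      policy = matrix(config$grid$levels[sol$policy_idx],
                      config$grid$n, config$T_horizon),
      policy_idx = sol$policy_idx,
      values = sol$values,
      config = config,
      config_hash = config_hash(config)
    ),
    class = "aware_sdp"
  )
}

#' @export
print.aware_sdp <- function(x, ...) {
  cat(sprintf(
    "<aware_sdp> %d states x %d epochs; decision range [%.2f, %.2f]; config %s\n",
    nrow(x$policy), ncol(x$policy), min(x$policy), max(x$policy), x$config_hash
  ))
  invisible(x)
}

#' Exact value of a fixed policy under the planner's objective
#'
#' Evaluates a given policy with the same direction-weighted, discounted
#' backup recursion the solver maximises — the planner's own objective. By
#' construction the solved policy's value dominates every other policy's
#' value state by state.
#'
#' @param config An [aware_config()] object.
#' @param policy An `aware_sdp` object, a single decision value (a constant
#'   policy, e.g. the habitual policy's mean action), or a states x epochs
#'   matrix of decision values on the grid.
#' @return A states x (epochs + 1) value matrix; entry `[i, 1]` is the value
#'   of starting at the i-th grid level at epoch 0.
#' @export
evaluate_policy <- function(config, policy) {
  inst <- as_instance(config)
  grid <- config$grid
  pol_idx <- if (inherits(policy, "aware_sdp")) {
    policy$policy_idx
  } else if (is.numeric(policy) && length(policy) == 1L) {
    matrix(snap_to_grid(policy, grid, warn = FALSE),
           grid$n, config$T_horizon)
  } else {
    m <- as.matrix(policy)
    if (!all(dim(m) == c(grid$n, config$T_horizon))) {
      abort("`policy` matrix must be n_states x T_horizon.")
    }
    matrix(snap_to_grid(as.vector(m), grid, warn = FALSE),
           grid$n, config$T_horizon)
  }
  evaluate_policy_instance(inst, pol_idx)
}
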