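#' Simulate one trajectory
#'
#' Rolls the awareness state forward for one individual: at each epoch the
#' decision is looked up from the self-aware policy or drawn from the habitual
#' sampler, the transition probabilities are evaluated at that decision, a
#' shock is sampled, and the state takes one clamped grid step. Stage rewards
#' are recorded unweighted (the planner's direction weights and discounting
#' apply only inside the policy computation), and the terminal reward is
#' collected at the horizon.
#'
#' @param policy Either an `aware_sdp` object (self-aware policy) or the
#'   string `"habitual"`.
#' @param config An [aware_config()] object; required when `policy` is
#'   `"habitual"`, otherwise taken from the `aware_sdp` object unless
#'   supplied.
#' @param seed Integer seed; mandatory, every reported number must be
#'   reproducible from `(config, seed)`.
#' @return An object of class `aware_trajectory`; its `data` element is a
#'   tibble with columns `epoch`, `state`, `decision`, `shock`,
#'   `stage_reward`, `cum_reward` (decision/shock/stage reward are `NA` at the
#'   terminal epoch, where `cum_reward` includes the terminal reward).
#' @examples
#' cfg <- aware_config(p_r = 0.6, sigma = 0.08, s0 = 0.2, T_horizon = 20, N = 1)
#' tr <- run_trajectory("habitual", cfg, seed = 42)
#' tail(tidy(tr), 3)
#' @export
run_trajectory <- function(policy, config = NULL, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: trajectories must be reproducible.")
  }
  mode <- policy_mode(policy)
  if (is.null(config)) {
    if (mode != "optimal") abort("`config` is required for the habitual policy.")
    config <- policy$config
  }
  set.seed(seed)
  sim <- simulate_path(policy, config, mode)
  term <- terminal_reward(sim$states[config$T_horizon + 1L], config$rewards)
  data <- tibble::tibble(
    epoch = 0:config$T_horizon,
    state = sim$states,
    decision = c(sim$decisions, NA_real_),
    shock = c(sim$shocks, NA_integer_),
    stage_reward = c(sim$stage_rewards, NA_real_),
    cum_reward = cumsum(c(sim$stage_rewards, term))
  )
  structure(
    list(data = data, mode = mode, seed = seed,
         terminal_reward = term, config = config,
         config_hash = config_hash(config)),
    class = "aware_trajectory"
  )
}

policy_mode <- function(policy) {
  if (inherits(policy, "aware_sdp")) return("optimal")
  if (identical(policy, "habitual")) return("habitual")
  abort("`policy` must be an `aware_sdp` object or the string \"habitual\".")
}

# one path under the current RNG state; states tracked by grid index
simulate_path <- function(policy, config, mode) {
  grid <- config$grid
  T_h <- config$T_horizon
  n <- grid$n
  P <- transition_matrix(grid$levels, config$p_r, config$shape)
  c_up <- P[, 1]
  c_stay <- P[, 1] + P[, 2]
  s_idx <- integer(T_h + 1L)
  s_idx[1L] <- if (config$s0_mode == "fixed") {
    snap_to_grid(config$s0, grid, warn = FALSE)
  } else {
    sample.int(n, 1L)
  }
  if (mode == "habitual") {
    e <- rnorm(T_h, config$p_r, config$sigma)
    u_idx <- pmin(pmax(round(e / grid$step), 1L), n)
  } else {
    u_idx <- integer(T_h) # filled along the path
  }
  r <- runif(T_h)
  shocks <- integer(T_h)
  for (t in seq_len(T_h)) {
    i <- s_idx[t]
    a <- if (mode == "habitual") u_idx[t] else policy$policy_idx[i, t]
    if (mode != "habitual") u_idx[t] <- a
    w <- if (r[t] < c_up[a]) 1L else if (r[t] < c_stay[a]) 0L else -1L
    shocks[t] <- w
    s_idx[t + 1L] <- min(max(i + w, 1L), n)
  }
  states <- grid$levels[s_idx]
  decisions <- grid$levels[u_idx]
  list(
    states = states, decisions = decisions, shocks = shocks,
    stage_rewards = stage_reward(states[seq_len(T_h)], decisions,
                                 config$rewards)
  )
}

#' Simulate a Monte Carlo ensemble
#'
#' Runs `N` independent trajectories with per-run seeds derived
#' deterministically from `master_seed` (the run seeds are drawn by
#' `sample.int()` under `set.seed(master_seed)`), and aggregates per-epoch
#' means and standard errors of state, decision and stage reward, plus the
#' mean cumulative-reward path.
#'
#' @inheritParams run_trajectory
#' @param N Ensemble size; defaults to `config$N`.
#' @param master_seed Integer master seed (mandatory).
#' @return An object of class `aware_ensemble` with elements `summary` (a
#'   per-epoch tibble), `final_states` (length-`N` vector), `mode`, `N`,
#'   `master_seed`, `config` and `config_hash`.
#' @export
run_ensemble <- function(policy, config = NULL, N = NULL, master_seed) {
  if (missing(master_seed) || is.null(master_seed)) {
    abort("`master_seed` is required: ensembles must be reproducible.")
  }
  mode <- policy_mode(policy)
  if (is.null(config)) {
    if (mode != "optimal") abort("`config` is required for the habitual policy.")
    config <- policy$config
  }
  N <- as.integer(N %||% config$N)
  stopifnot(N >= 1L)
  T_h <- config$T_horizon
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, N)

  states <- matrix(0, N, T_h + 1L)
  decisions <- matrix(0, N, T_h)
  rewards <- matrix(0, N, T_h)
  terminal <- numeric(N)
  for (i in seq_len(N)) {
    set.seed(seeds[i])
    sim <- simulate_path(policy, config, mode)
    states[i, ] <- sim$states
    decisions[i, ] <- sim$decisions
    rewards[i, ] <- sim$stage_rewards
    terminal[i] <- terminal_reward(sim$states[T_h + 1L], config$rewards)
  }
  cum <- t(apply(cbind(rewards, terminal), 1L, cumsum))
  se <- function(m) apply(m, 2L, stats::sd) / sqrt(nrow(m))
  summary <- tibble::tibble(
    epoch = 0:T_h,
    mean_state = colMeans(states),
    se_state = se(states),
    mean_decision = c(colMeans(decisions), NA_real_),
    se_decision = c(se(decisions), NA_real_),
    mean_stage_reward = c(colMeans(rewards), NA_real_),
    se_stage_reward = c(se(rewards), NA_real_),
    mean_cum_reward = unname(colMeans(cum))
  )
  structure(
    list(summary = summary, final_states = states[, T_h + 1L],
         mode = mode, N = N, master_seed = master_seed,
         config = config, config_hash = config_hash(config)),
    class = "aware_ensemble"
  )
}

#' @export
print.aware_ensemble <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<aware_ensemble> %s policy, N = %d, T = %d; final mean state %.3f (se %.4f)\n",
    x$mode, x$N, x$config$T_horizon, fin$mean_state, fin$se_state
  ))
  invisible(x)
}

#' @export
print.aware_trajectory <- function(x, ...) {
  cat(sprintf(
    "<aware_trajectory> %s policy, T = %d, seed %d; final state %.2f, total reward %.3f\n",
    x$mode, x$config$T_horizon, x$seed, x$data$state[nrow(x$data)],
    x$data$cum_reward[nrow(x$data)]
  ))
  invisible(x)
}

#' Compare habitual and self-aware behaviour under one configuration
#'
#' Solves the self-aware policy, simulates both ensembles, and aligns their
#' per-epoch summaries on a shared epoch axis together with their
#' differences (self-aware minus habitual).
#'
#' @param config An [aware_config()] object.
#' @param master_seed Integer master seed; two sub-seeds (one per policy) are
#'   derived from it.
#' @param N Ensemble size override (defaults to `config$N`).
#' @return An object of class `aware_comparison` with elements `habitual` and
#'   `self_aware` (both `aware_ensemble`), `sdp`, and `differences` (a
#'   per-epoch tibble of mean differences).
#' @export
compare_policies <- function(config, master_seed, N = NULL) {
  if (missing(master_seed) || is.null(master_seed)) {
    abort("`master_seed` is required.")
  }
  set.seed(master_seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  sdp <- solve_sdp(config)
  hab <- run_ensemble("habitual", config, N = N, master_seed = sub[1])
  opt <- run_ensemble(sdp, config, N = N, master_seed = sub[2])
  differences <- tibble::tibble(
    epoch = hab$summary$epoch,
    d_mean_state = opt$summary$mean_state - hab$summary$mean_state,
    d_mean_decision = opt$summary$mean_decision - hab$summary$mean_decision,
    d_mean_cum_reward = opt$summary$mean_cum_reward - hab$summary$mean_cum_reward
  )
  structure(
    list(habitual = hab, self_aware = opt, sdp = sdp,
         differences = differences, master_seed = master_seed,
         config = config, config_hash = config_hash(config)),
    class = "aware_comparison"
  )
}

#' @export
print.aware_comparison <- function(x, ...) {
  n <- nrow(x$differences)
  cat(sprintf(
    "<aware_comparison> final mean state: habitual %.3f, self-aware %.3f (diff %+.3f)\n",
    x$habitual$summary$mean_state[n], x$self_aware$summary$mean_state[n],
    x$differences$d_mean_state[n]
  ))
  invisible(x)
}
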