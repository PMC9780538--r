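#' Exact distribution propagation
#'
#' Pushes the full state-probability vector through the transition kernel
#' epoch by epoch, giving the exact mean state per epoch and the exact
#' expected (unweighted) cumulative reward — the noiseless counterpart of
#' [run_ensemble()]. For the habitual policy the kernel row is the exact
#' marginal over the clipped-and-snapped Gaussian action distribution; for a
#' self-aware policy the epoch- and state-dependent decisions are used.
#'
#' @inheritParams run_trajectory
#' @return A list with `by_epoch` (tibble: `epoch`, `mean_state`,
#'   `mean_decision`, `mean_stage_reward`), `distributions` (states x
#'   epochs+1 matrix of exact state probabilities) and
#'   `expected_cum_reward` (stage rewards plus terminal reward, unweighted).
#' @examples
#' cfg <- aware_config(p_r = 0.6, sigma = 0.08, s0 = 0.2, T_horizon = 10, N = 1)
#' propagate_exact("habitual", cfg)$by_epoch
#' @export
propagate_exact <- function(policy, config = NULL) {
  mode <- policy_mode(policy)
  if (is.null(config)) {
    if (mode != "optimal") abort("`config` is required for the habitual policy.")
    config <- policy$config
  }
  grid <- config$grid
  n <- grid$n
  T_h <- config$T_horizon
  P <- transition_matrix(grid$levels, config$p_r, config$shape)

  d <- numeric(n)
  if (config$s0_mode == "fixed") {
    d[snap_to_grid(config$s0, grid, warn = FALSE)] <- 1
  } else {
    d[] <- 1 / n
  }
  if (mode == "habitual") {
    w_act <- habitual_action_weights(config$p_r, config$sigma, grid)
    row_marg <- colSums(w_act * P) # same for every state
    u_mean_h <- sum(w_act * grid$levels)
  }
  dist <- matrix(0, n, T_h + 1L)
  dist[, 1L] <- d
  mean_state <- numeric(T_h + 1L)
  mean_decision <- numeric(T_h)
  mean_reward <- numeric(T_h)
  for (t in seq_len(T_h)) {
    mean_state[t] <- sum(d * grid$levels)
    if (mode == "habitual") {
      p_up <- rep(row_marg[1], n); p_stay <- rep(row_marg[2], n)
      p_down <- rep(row_marg[3], n)
      mean_decision[t] <- u_mean_h
    } else {
      a <- policy$policy_idx[, t]
      p_up <- P[a, 1]; p_stay <- P[a, 2]; p_down <- P[a, 3]
      mean_decision[t] <- sum(d * grid$levels[a])
    }
    mean_reward[t] <- config$rewards$alpha * mean_state[t] -
      config$rewards$beta * mean_decision[t]
    d_new <- numeric(n)
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    flux <- d * p_up
    d_new[1:n] <- d * p_stay
    for (j in seq_len(n)) d_new[up[j]] <- d_new[up[j]] + flux[j]
    flux <- d * p_down
    for (j in seq_len(n)) d_new[dn[j]] <- d_new[dn[j]] + flux[j]
    d <- d_new
    dist[, t + 1L] <- d
  }
  mean_state[T_h + 1L] <- sum(d * grid$levels)
  exp_terminal <- sum(d * terminal_reward(grid$levels, config$rewards))
  list(
    by_epoch = tibble::tibble(
      epoch = 0:T_h,
      mean_state = mean_state,
      mean_decision = c(mean_decision, NA_real_),
      mean_stage_reward = c(mean_reward, NA_real_)
    ),
    distributions = dist,
    expected_cum_reward = sum(mean_reward) + exp_terminal
  )
}

#' Hand-built tiny model instances
#'
#' A reduced model small enough for exhaustive policy enumeration, used as a
#' correctness oracle for the backward-induction solver: a handful of state
#' levels, a short horizon, a few actions with arbitrary (row-stochastic)
#' up/stay/down triples, arbitrary stage and terminal rewards, and either a
#' constant future weight or a state-dependent emotional one scaled by
#' `tau / horizon`.
#'
#' @param P `n_actions` x 3 matrix of up/stay/down probabilities; rows must
#'   sum to 1.
#' @param reward `n_states` x `n_actions` stage-reward matrix.
#' @param terminal Length-`n_states` terminal reward vector.
#' @param horizon Number of decision epochs.
#' @param gamma Length-3 positive direction weights.
#' @param delta Constant future weight (used when `delta_s` is `NULL`).
#' @param delta_s Optional length-`n_states` state-dependent discount vector;
#'   when given, the future weight at stage `tau` is `delta_s * tau /
#'   horizon` (the emotional mode).
#' @param u Optional action values (defaults to an equispaced grid in (0,1)),
#'   only used for reporting.
#' @return An object of class `aware_tiny_instance` sharing the internal
#'   instance structure of [solve_sdp()].
#' @export
tiny_instance <- function(P, reward, terminal, horizon,
                          gamma = c(1, 1, 1), delta = 0.9, delta_s = NULL,
                          u = NULL) {
  P <- as.matrix(P); reward <- as.matrix(reward)
  n_a <- nrow(P); n_s <- nrow(reward)
  if (ncol(P) != 3L || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    abort("`P` must be an n_actions x 3 row-stochastic matrix.")
  }
  if (ncol(reward) != n_a || length(terminal) != n_s) {
    abort("`reward` must be n_states x n_actions and `terminal` length n_states.")
  }
  if (!is.null(delta_s) && length(delta_s) != n_s) {
    abort("`delta_s` must have one entry per state.")
  }
  u <- u %||% seq_len(n_a) / (n_a + 1)
  discount <- if (is.null(delta_s)) {
    d <- rep(delta, n_s)
    function(tau) d
  } else {
    function(tau) delta_s * (tau / horizon)
  }
  structure(
    list(n_s = n_s, n_t = as.integer(horizon), u = u, P = P, reward = reward,
         terminal = terminal, gamma = gamma, discount = discount,
         delta = delta, delta_s = delta_s),
    class = "aware_tiny_instance"
  )
}

#' Random tiny instance
#'
#' Draws a random [tiny_instance()] under a fixed seed: Dirichlet transition
#' rows, Gaussian rewards, and (optionally) random direction weights and a
#' random state-dependent discount including negative low-state values.
#'
#' @param seed Integer seed.
#' @param n_states,n_actions,horizon Instance dimensions.
#' @param gamma_mode `"unit"` for (1,1,1) or `"random"` for positive random
#'   weights (possibly above 1).
#' @param emotion Draw a state-dependent discount vector (emotional mode)?
#' @return An `aware_tiny_instance`.
#' @export
random_tiny_instance <- function(seed, n_states = 3, n_actions = 3,
                                 horizon = 2, gamma_mode = c("random", "unit"),
                                 emotion = FALSE) {
  gamma_mode <- match.arg(gamma_mode)
  set.seed(seed)
  P <- t(replicate(n_actions, {
    x <- rgamma(3, shape = 1)
    x / sum(x)
  }))
  reward <- matrix(rnorm(n_states * n_actions), n_states, n_actions)
  terminal <- rnorm(n_states)
  gamma <- if (gamma_mode == "unit") c(1, 1, 1) else runif(3, 0.05, 3)
  delta_s <- if (emotion) sort(runif(n_states, -0.5, 1)) else NULL
  tiny_instance(P, reward, terminal, horizon, gamma = gamma,
                delta = runif(1, 0.5, 0.99), delta_s = delta_s)
}

#' Solve or evaluate a tiny instance
#'
#' `solve_tiny()` runs the same backward-induction core as [solve_sdp()] on a
#' [tiny_instance()]. `evaluate_tiny_policy()` evaluates a fixed policy
#' (state x epoch action-index matrix) under the same direction-weighted
#' backup semantics.
#'
#' @param instance An `aware_tiny_instance`.
#' @param policy_idx Integer `n_states` x `horizon` matrix of action indices.
#' @return `solve_tiny()`: a list with `policy_idx` and `values`;
#'   `evaluate_tiny_policy()`: the value matrix (states x epochs + 1).
#' @export
solve_tiny <- function(instance) {
  stopifnot(inherits(instance, "aware_tiny_instance"))
  solve_instance(instance)
}

#' @rdname solve_tiny
#' @export
evaluate_tiny_policy <- function(instance, policy_idx) {
  stopifnot(inherits(instance, "aware_tiny_instance"))
  evaluate_policy_instance(instance, as.matrix(policy_idx))
}

# independent plain-expectation policy evaluation (only valid for
# gamma = (1,1,1) and a constant discount): builds full state-transition
# matrices per epoch and applies the textbook recursion by matrix products.
evaluate_tiny_policy_plain <- function(instance, policy_idx) {
  stopifnot(is.null(instance$delta_s))
  n_s <- instance$n_s; n_t <- instance$n_t
  up <- pmin(seq_len(n_s) + 1L, n_s)
  dn <- pmax(seq_len(n_s) - 1L, 1L)
  V <- instance$terminal
  for (tau in seq(n_t - 1L, 0L)) {
    a <- policy_idx[, tau + 1L]
    M <- matrix(0, n_s, n_s)
    for (s in seq_len(n_s)) {
      M[s, up[s]] <- M[s, up[s]] + instance$P[a[s], 1]
      M[s, s] <- M[s, s] + instance$P[a[s], 2]
      M[s, dn[s]] <- M[s, dn[s]] + instance$P[a[s], 3]
    }
    V <- instance$reward[cbind(seq_len(n_s), a)] + instance$delta * (M %*% V)
  }
  drop(V)
}

#' Exhaustive policy search on a tiny instance
#'
#' Enumerates every deterministic state-and-epoch-to-action mapping of a
#' [tiny_instance()], evaluates each under the same direction-weighted backup
#' semantics as the solver, and returns the best initial-state value. The
#' enumeration size `n_actions^(n_states * horizon)` must not exceed `1e6`.
#'
#' @param instance An `aware_tiny_instance`.
#' @param s0_idx State index whose initial value is maximised (default 1).
#' @return A list with `value` (the maximal value at `(s0_idx, epoch 0)`),
#'   `policy_idx` (one maximising policy) and `n_policies`.
#' @export
exhaustive_best_policy <- function(instance, s0_idx = 1L) {
  stopifnot(inherits(instance, "aware_tiny_instance"))
  n_cells <- instance$n_s * instance$n_t
  n_pol <- instance$n_a %||% nrow(instance$P)
  total <- n_pol^n_cells
  if (total > 1e6) {
    abort(sprintf("Enumeration size %.3g exceeds the 1e6 bound.", total))
  }
  best_val <- -Inf
  best_pol <- NULL
  idx <- rep(1L, n_cells)
  for (k in seq_len(total)) {
    pol <- matrix(idx, instance$n_s, instance$n_t)
    V <- evaluate_policy_instance(instance, pol)
    v0 <- V[s0_idx, 1L]
    if (v0 > best_val) {
      best_val <- v0
      best_pol <- pol
    }
    # increment mixed-radix counter
    j <- 1L
    while (j <= n_cells) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= n_pol) break
      idx[j] <- 1L
      j <- j + 1L
    }
  }
  list(value = best_val, policy_idx = best_pol, n_policies = total)
}

#' Serialize tiny instances as JSON
#'
#' @param instance An `aware_tiny_instance`.
#' @param path File path.
#' @return `write_tiny_instance()` returns `path` invisibly;
#'   `read_tiny_instance()` returns an `aware_tiny_instance`.
#' @export
write_tiny_instance <- function(instance, path) {
  x <- list(
    P = instance$P, reward = instance$reward, terminal = instance$terminal,
    horizon = instance$n_t, gamma = instance$gamma, delta = instance$delta,
    delta_s = instance$delta_s, u = instance$u
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tiny_instance
#' @export
read_tiny_instance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tiny_instance(x$P, x$reward, x$terminal, x$horizon, gamma = x$gamma,
                delta = x$delta, delta_s = x$delta_s, u = x$u)
}
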