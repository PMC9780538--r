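test_that("habitual decisions are noisy copies of the propensity", {
  g <- state_grid()
  expect_equal(habitual_action(5, p_r = 0.6, sigma = 0), rep(0.6, 5))
  expect_equal(habitual_action(1, p_r = 0.637, sigma = 0), 0.64) # snapped
  set.seed(5)
  n <- 1e5
  u <- habitual_action(n, p_r = 0.6, sigma = 0.08)
  expect_true(all(u >= g$lower_bound & u <= g$upper_bound))
  expect_true(all(u %in% g$levels))
  # clipping/snapping bias is negligible at this sigma
  expect_lt(abs(mean(u) - 0.6), 3 * 0.08 / sqrt(n))
})

test_that("a single backup matches a hand computation at the last stage", {
  cfg <- small_config(T_horizon = 10)
  g <- cfg$grid
  v_T <- terminal_reward(g$levels, cfg$rewards)
  s <- 0.40; u <- 0.30
  i <- 40L
  row <- transition_row(u, cfg$p_r, cfg$shape)
  by_hand <- (cfg$rewards$alpha * s - cfg$rewards$beta * u) +
    cfg$rewards$delta * (3 * v_T[41] * row$p_up +
                         1 * v_T[40] * row$p_stay +
                         0.1 * v_T[39] * row$p_down)
  expect_equal(bellman_backup(s, u, v_T, tau = 9, cfg), by_hand,
               tolerance = 1e-12)
})

test_that("boundary backups use the clamped neighbour's value", {
  cfg <- small_config(T_horizon = 5)
  g <- cfg$grid
  v <- seq_len(g$n) * 1.0
  row <- transition_row(0.5, cfg$p_r, cfg$shape)
  top <- bellman_backup(g$upper_bound, 0.5, v, tau = 2, cfg)
  by_hand <- stage_reward(g$upper_bound, 0.5, cfg$rewards) +
    cfg$rewards$delta * (3 * v[g$n] * row$p_up + v[g$n] * row$p_stay +
                         0.1 * v[g$n - 1] * row$p_down)
  expect_equal(top, by_hand, tolerance = 1e-12)
})

test_that("with emotions the first-epoch backup is purely myopic", {
  cfg <- small_config(T_horizon = 10, emotions = TRUE)
  v <- runif(cfg$grid$n, 0, 100)
  expect_equal(bellman_backup(0.3, 0.7, v, tau = 0, cfg),
               stage_reward(0.3, 0.7, cfg$rewards))
})

test_that("a one-stage programme equals a direct scan over the action grid", {
  cfg <- small_config(T_horizon = 1)
  fit <- solve_sdp(cfg)
  g <- cfg$grid
  v_T <- terminal_reward(g$levels, cfg$rewards)
  for (i in c(1L, 25L, 50L, 99L)) {
    q <- vapply(g$levels, function(u) {
      bellman_backup(g$levels[i], u, v_T, tau = 0, cfg)
    }, numeric(1))
    expect_equal(fit$policy_idx[i, 1], which.max(q))
    expect_equal(fit$values[i, 1], max(q), tolerance = 1e-12)
  }
})

test_that("the value table is anchored at the terminal reward", {
  cfg <- small_config(T_horizon = 7)
  fit <- solve_sdp(cfg)
  expect_equal(fit$values[, 8], terminal_reward(cfg$grid$levels, cfg$rewards))
  expect_true(all(is.finite(fit$values)))
  expect_true(all(fit$policy %in% cfg$grid$levels))
  expect_equal(dim(fit$policy), c(cfg$grid$n, 7L))
})

test_that("solving is deterministic", {
  cfg <- small_config(T_horizon = 15)
  f1 <- solve_sdp(cfg)
  f2 <- solve_sdp(cfg)
  expect_identical(f1$policy, f2$policy)
  expect_identical(f1$values, f2$values)
})

test_that("argmax ties break toward the smallest decision", {
  # two identical actions: every state/epoch must pick the first one
  P <- rbind(c(0.4, 0.3, 0.3), c(0.4, 0.3, 0.3))
  inst <- tiny_instance(P, reward = matrix(1, 3, 2), terminal = c(0, 1, 2),
                        horizon = 3, gamma = c(2, 1, 0.5), delta = 0.9)
  sol <- solve_tiny(inst)
  expect_true(all(sol$policy_idx == 1L))
})

test_that("backward induction equals exhaustive enumeration on tiny instances", {
  for (inst in oracle_instances(20)) {
    sol <- solve_tiny(inst)
    best <- exhaustive_best_policy(inst, s0_idx = 1L)
    expect_equal(sol$values[1, 1], best$value, tolerance = 1e-9)
  }
})

test_that("unit direction weights reduce to the textbook expectation", {
  inst <- random_tiny_instance(77, n_states = 4, n_actions = 3, horizon = 3,
                               gamma_mode = "unit")
  sol <- solve_tiny(inst)
  # independent textbook recursion with explicit transition matrices
  n_s <- inst$n_s
  up <- pmin(seq_len(n_s) + 1L, n_s); dn <- pmax(seq_len(n_s) - 1L, 1L)
  V <- inst$terminal
  pol <- matrix(NA_integer_, n_s, inst$n_t)
  for (tau in seq(inst$n_t - 1L, 0L)) {
    Q <- matrix(NA_real_, n_s, nrow(inst$P))
    for (a in seq_len(nrow(inst$P))) {
      ev <- inst$P[a, 1] * V[up] + inst$P[a, 2] * V + inst$P[a, 3] * V[dn]
      Q[, a] <- inst$reward[, a] + inst$delta * ev
    }
    pol[, tau + 1L] <- apply(Q, 1, which.max)
    V <- apply(Q, 1, max)
  }
  expect_equal(sol$values[, 1], V, tolerance = 1e-12)
  expect_equal(sol$policy_idx, pol)
  # and the gamma-weighted evaluator agrees with the plain-expectation path
  plain <- awaremdp:::evaluate_tiny_policy_plain(inst, sol$policy_idx)
  expect_equal(evaluate_tiny_policy(inst, sol$policy_idx)[, 1], plain,
               tolerance = 1e-12)
})

test_that("the solved policy dominates fixed policies under the planner objective", {
  cfg <- small_config(T_horizon = 40)
  fit <- solve_sdp(cfg)
  v_opt <- evaluate_policy(cfg, fit)
  # state-by-state dominance over the habitual mean action and random policies
  v_hab <- evaluate_policy(cfg, cfg$p_r)
  tol <- 1e-9 * pmax(abs(v_opt[, 1]), 1)
  expect_true(all(v_opt[, 1] - v_hab[, 1] >= -tol))
  set.seed(21)
  for (k in 1:3) {
    pol <- matrix(sample(cfg$grid$levels, cfg$grid$n * 40, replace = TRUE),
                  cfg$grid$n, 40)
    v_rnd <- evaluate_policy(cfg, pol)
    expect_true(all(v_opt[, 1] - v_rnd[, 1] >= -tol))
  }
  # the solver's own value table equals the evaluation of its policy
  expect_equal(v_opt, fit$values, tolerance = 1e-12)
})

test_that("values respect the horizon bound when backups are contractive", {
  cfg <- small_config(T_horizon = 25, gamma = c(1, 1, 1))
  fit <- solve_sdp(cfg)
  g <- cfg$grid
  max_r <- max(abs(outer(cfg$rewards$alpha * g$levels,
                         cfg$rewards$beta * g$levels, `-`)))
  bound <- 25 * max_r + max(terminal_reward(g$levels, cfg$rewards))
  expect_true(all(abs(fit$values) <= bound + 1e-9))
})
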