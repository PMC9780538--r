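test_that("a frozen kernel keeps the state at its start", {
  cfg <- small_config(T_horizon = 60, shape = frozen_shape())
  tr <- run_trajectory("habitual", cfg, seed = 9)
  expect_true(all(tr$data$state == 0.2))
  expect_true(all(tr$data$shock[1:60] == 0L))
})

test_that("trajectories are reproducible and internally consistent", {
  cfg <- small_config(T_horizon = 30)
  fit <- solve_sdp(cfg)
  t1 <- run_trajectory(fit, seed = 123)
  t2 <- run_trajectory(fit, seed = 123)
  expect_identical(t1$data, t2$data)
  expect_error(run_trajectory(fit), "seed")

  d <- t1$data
  g <- cfg$grid
  # states never leave the grid and follow the recorded shocks
  expect_true(all(d$state >= g$lower_bound & d$state <= g$upper_bound))
  expect_equal(d$state[-1],
               step_state(d$state[-31], d$shock[-31], g))
  # decisions lie on the action grid and follow the policy
  expect_true(all(d$decision[1:30] %in% g$levels))
  idx <- snap_to_grid(d$state[1:30], g, warn = FALSE)
  expect_equal(d$decision[1:30],
               fit$policy[cbind(idx, 1:30)])
  # accounting identity: cumulative = stage rewards + terminal
  expect_equal(d$cum_reward[31],
               sum(d$stage_reward[1:30]) + t1$terminal_reward)
  expect_equal(d$stage_reward[1:30],
               stage_reward(d$state[1:30], d$decision[1:30], cfg$rewards))
})

test_that("an ensemble of one equals its single trajectory", {
  cfg <- small_config(T_horizon = 25)
  ens <- run_ensemble("habitual", cfg, N = 1, master_seed = 77)
  set.seed(77)
  seed1 <- sample.int(.Machine$integer.max - 1L, 1L)
  tr <- run_trajectory("habitual", cfg, seed = seed1)
  expect_equal(ens$summary$mean_state, tr$data$state)
  expect_equal(ens$summary$mean_decision, tr$data$decision)
  expect_equal(ens$summary$mean_cum_reward, tr$data$cum_reward)
})

test_that("ensembles are reproducible from (config, master seed)", {
  cfg <- small_config(T_horizon = 20, N = 40)
  e1 <- run_ensemble("habitual", cfg, master_seed = 5)
  e2 <- run_ensemble("habitual", cfg, master_seed = 5)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$final_states, e2$final_states)
  e3 <- run_ensemble("habitual", cfg, master_seed = 6)
  expect_false(identical(e1$summary, e3$summary))
  expect_error(run_ensemble("habitual", cfg), "master_seed")
})

test_that("ensemble means track the exact distribution propagation", {
  cfg <- small_config(T_horizon = 40, N = 500)
  fit <- solve_sdp(cfg)
  for (pol in list("habitual", fit)) {
    ens <- run_ensemble(pol, cfg, master_seed = 31)
    ex <- propagate_exact(pol, cfg)
    z <- (ens$summary$mean_state - ex$by_epoch$mean_state) /
      pmax(ens$summary$se_state, 1e-12)
    # checked at a handful of well-separated epochs to keep the joint
    # false-alarm probability of the 3-SE band negligible
    expect_true(all(abs(z[c(11, 21, 31, 41)]) < 3))
  }
})

test_that("Monte Carlo error shrinks as one over root N", {
  cfg <- small_config(T_horizon = 30)
  v1 <- run_ensemble("habitual", cfg, N = 300, master_seed = 2)$summary$se_state
  v2 <- run_ensemble("habitual", cfg, N = 600, master_seed = 3)$summary$se_state
  ratio <- mean(v1[-1]^2 * 300) / mean(v2[-1]^2 * 600) # per-run variance ratio
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
  # doubling N roughly halves the variance of the mean
  expect_gt(mean(v1[-1]^2) / mean(v2[-1]^2), 1.5)
  expect_lt(mean(v1[-1]^2) / mean(v2[-1]^2), 2.5)
})

test_that("uniform initial states cover the grid", {
  cfg <- aware_config(p_r = 0.5, sigma = 0.1, s0_mode = "uniform",
                      T_horizon = 2, N = 400)
  ens <- run_ensemble("habitual", cfg, master_seed = 13)
  s0 <- ens$summary$mean_state[1]
  # mean of a uniform draw over the grid is 0.5
  se <- sqrt(1 / 12) / sqrt(400)
  expect_lt(abs(s0 - 0.5), 4 * se)
})

test_that("policy comparison aligns both ensembles and their differences", {
  cfg <- small_config(T_horizon = 25, N = 60)
  cmp <- compare_policies(cfg, master_seed = 8)
  expect_equal(cmp$differences$d_mean_state,
               cmp$self_aware$summary$mean_state -
                 cmp$habitual$summary$mean_state)
  expect_equal(nrow(cmp$differences), 26)
  td <- tidy(cmp)
  expect_equal(unique(td$mode), c("habitual", "self_aware"))
  # comparing a policy with itself leaves no difference
  e1 <- run_ensemble("habitual", cfg, master_seed = 99)
  e2 <- run_ensemble("habitual", cfg, master_seed = 99)
  expect_true(all(e1$summary$mean_state - e2$summary$mean_state == 0))
})
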