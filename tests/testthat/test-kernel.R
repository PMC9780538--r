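test_that("base curves hit their pinned peak and floor", {
  sh <- curve_shape()
  expect_equal(base_forward_analytical(sh$peak_analytical, sh), sh$p_peak)
  expect_equal(base_forward_intuitive(sh$peak_intuitive, sh), sh$p_peak)
  # both curves fall to the floor at the interval ends (the half-power tail
  # of the default bump approaches it slowly, hence the one-sided check)
  expect_lt(base_forward_analytical(1e-9, sh), sh$p_floor + 1e-4)
  expect_lt(base_forward_intuitive(1 - 1e-9, sh), sh$p_floor + 1e-4)
  expect_lt(base_forward_intuitive(1e-12, sh), sh$p_floor + 1e-4)
  expect_gte(base_forward_intuitive(1e-12, sh), sh$p_floor)
})

test_that("sharp shape reproduces the closed-form worked values", {
  sh <- sharp_shape() # exponents (4, 1), floor 0.05, peak 0.85
  # independent arithmetic: 0.05 + 0.80 * 0.5^5 / (0.8^4 * 0.2)
  expect_equal(base_forward_analytical(0.5, sh),
               0.05 + 0.80 * 0.5^5 / (0.8^4 * 0.2), tolerance = 1e-12)
  # normalisation constant equals the numeric maximum of the bare bump
  u <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  expect_equal(max(u^4 * (1 - u)), 0.8^4 * 0.2, tolerance = 1e-6)
  # mixture is the plain average when both curves agree by symmetry
  expect_equal(forward_prob(0.5, 0.5, sh), base_forward_analytical(0.5, sh))
  row <- transition_row(0.5, 0.5, sh)
  expect_equal(row$p_up, 0.3551758, tolerance = 1e-6)
  expect_equal(row$p_stay, 0.1)
  expect_equal(row$p_down, 0.5448242, tolerance = 1e-6)
})

test_that("intuitive curve mirrors the analytical curve for symmetric peaks", {
  sh <- curve_shape()
  u <- seq(0.01, 0.99, by = 0.01)
  expect_equal(base_forward_intuitive(u, sh),
               base_forward_analytical(1 - u, sh), tolerance = 1e-12)
})

test_that("forward_prob is the convex combination of the base curves", {
  sh <- curve_shape()
  u <- seq(0.05, 0.95, by = 0.05)
  expect_equal(forward_prob(u, 1, sh), base_forward_analytical(u, sh))
  expect_equal(forward_prob(u, 0, sh), base_forward_intuitive(u, sh))
  expect_equal(forward_prob(u, 0.3, sh),
               0.3 * base_forward_analytical(u, sh) +
                 0.7 * base_forward_intuitive(u, sh))
})

test_that("domain violations raise errors", {
  expect_error(base_forward_analytical(0), "open interval")
  expect_error(base_forward_analytical(1), "open interval")
  expect_error(forward_prob(0.5, -0.1), "p_r")
  expect_error(forward_prob(0.5, 1.1), "p_r")
  expect_error(curve_shape(p_peak = 0.95, p_stay = 0.1), "probability budget")
  expect_error(curve_shape(peak_analytical = 0.2, peak_intuitive = 0.8))
})

test_that("transition rows are row-stochastic for every action and propensity", {
  g <- state_grid()
  for (pr in seq(0, 1, by = 0.1)) {
    row <- transition_row(g$levels, pr, curve_shape())
    expect_true(all(row$p_up >= 0 & row$p_up <= 1))
    expect_true(all(row$p_down >= 0 & row$p_down <= 1))
    expect_true(all(abs(row$p_up + row$p_stay + row$p_down - 1) < 1e-12))
  }
})

test_that("mixture is monotone in propensity on the outer decision ranges", {
  sh <- curve_shape()
  g <- state_grid()
  prs <- seq(0, 1, by = 0.1)
  low_u <- g$levels[g$levels < sh$peak_intuitive]
  high_u <- g$levels[g$levels > sh$peak_analytical]
  for (u in low_u) {
    expect_true(all(diff(forward_prob(u, prs, sh)) <= 1e-12))
  }
  for (u in high_u) {
    expect_true(all(diff(forward_prob(u, prs, sh)) >= -1e-12))
  }
})

test_that("each base curve has exactly one local maximum on the decision grid", {
  g <- state_grid()
  for (f in list(base_forward_analytical, base_forward_intuitive)) {
    for (sh in list(curve_shape(), sharp_shape())) {
      v <- f(g$levels, sh)
      s <- sign(diff(v))
      # one sign change, from rising to falling
      expect_equal(sum(diff(s) != 0), 1L)
      expect_true(s[1] > 0 && s[length(s)] < 0)
    }
  }
})

test_that("sample_shock follows the row probabilities", {
  expect_true(all(sample_shock(c(1, 0, 0), 100) == 1L))
  expect_true(all(sample_shock(c(0, 0, 1), 100) == -1L))
  row <- transition_row(0.5, 0.5, sharp_shape())
  set.seed(7)
  n <- 1e5
  w <- sample_shock(row, n)
  for (pair in list(c(1, row$p_up), c(0, row$p_stay), c(-1, row$p_down))) {
    p <- pair[2]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(w == pair[1]) - p), 3 * se)
  }
  expect_error(sample_shock(c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("step_state takes single clamped grid steps", {
  expect_equal(step_state(0.20, +1), 0.21)
  expect_equal(step_state(0.99, +1), 0.99)
  expect_equal(step_state(0.01, -1), 0.01)
  g <- state_grid()
  set.seed(11)
  s <- sample(g$levels, 200, replace = TRUE)
  w <- sample(c(-1L, 0L, 1L), 200, replace = TRUE)
  out <- step_state(s, w, g)
  expect_true(all(out >= g$lower_bound & out <= g$upper_bound))
  expect_true(all(abs(out / g$step - round(out / g$step)) < 1e-9))
})

test_that("off-grid states snap to the nearest level with a warning", {
  expect_warning(i <- snap_to_grid(0.20499), "snapped")
  expect_equal(i, 20L)
  expect_silent(snap_to_grid(0.20))
})

test_that("transition_curves tabulates the kernel over the decision grid", {
  tc <- transition_curves(c(0, 1))
  expect_s3_class(tc, "tbl_df")
  expect_equal(nrow(tc), 2 * 99)
  expect_true(all(abs(tc$p_up + tc$p_stay + tc$p_down - 1) < 1e-12))
})
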