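# Shared fixtures: small configurations and tiny oracle instances, all built
# in code at test time.

small_config <- function(T_horizon = 20, N = 50, ...) {
  aware_config(p_r = 0.6, sigma = 0.08, s0 = 0.2,
               T_horizon = T_horizon, N = N, ...)
}

# the historically pinned sharp curve shape (beta-bump exponents (4, 1) /
# (1, 4), peak probability 0.85) used by the closed-form worked examples
sharp_shape <- function() curve_shape(p_peak = 0.85, concentration = 5)

# a near-frozen kernel: forward/backward probability ~1e-12, stay ~1
frozen_shape <- function() {
  curve_shape(p_floor = 0, p_peak = 1e-12, p_stay = 1 - 1e-12)
}

# deterministic batch of oracle instances spanning gamma modes, emotion-mode
# discounting and several sizes; enumeration sizes stay far below the 1e6
# bound so the whole batch runs in seconds
oracle_instances <- function(n = 20) {
  dims <- list(c(3, 3, 2), c(4, 2, 3), c(3, 2, 3), c(2, 3, 3), c(5, 2, 2))
  lapply(seq_len(n), function(i) {
    d <- dims[[(i - 1) %% length(dims) + 1]]
    random_tiny_instance(
      seed = 1000 + i,
      n_states = d[1], n_actions = d[2], horizon = d[3],
      gamma_mode = if (i %% 4 == 0) "unit" else "random",
      emotion = i %% 3 == 0
    )
  })
}
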