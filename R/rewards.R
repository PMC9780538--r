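#' Reward parameters
#'
#' The stage reward is linear in state and decision, `r(s, u) = alpha*s -
#' beta*u`: awareness is intrinsically valuable while analytical reasoning is
#' resource-consuming. The terminal reward is a normalised exponential in the
#' final state, `R * (exp(k*s) - 1) / (exp(k) - 1)`, pushing the final state
#' as high as possible. `gamma` holds the direction weights (up, stay, down)
#' applied inside the Bellman backup, and `delta` the constant future-reward
#' weight used when emotions are disabled.
#'
#' @param alpha Weight of awareness in the stage reward (> 0).
#' @param beta Cost weight of analyticity in the stage reward (> 0).
#' @param gamma Length-3 vector of positive direction weights for the
#'   up/stay/down terms of the backup. Values above 1 are accepted (the
#'   backup is a distorted, non-normalised expectation).
#' @param delta Constant future-reward weight in (0, 1).
#' @param terminal_scale Terminal reward at full awareness (default 10).
#' @param terminal_rate Exponential rate of the terminal reward (default 5).
#' @return An object of class `aware_reward_params`.
#' @export
reward_params <- function(alpha = 1, beta = 1.5, gamma = c(3, 1, 0.1),
                          delta = 0.75, terminal_scale = 10,
                          terminal_rate = 5) {
  problems <- character()
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0)) {
    problems <- c(problems, "alpha must be a single positive number")
  }
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 0)) {
    problems <- c(problems, "beta must be a single positive number")
  }
  if (!(is.numeric(gamma) && length(gamma) == 3L && all(gamma > 0))) {
    problems <- c(problems, "gamma must be a length-3 positive vector")
  }
  if (!(is.numeric(delta) && length(delta) == 1L && delta > 0 && delta < 1)) {
    problems <- c(problems, "delta must be a single number in (0, 1)")
  }
  if (!(terminal_scale > 0 && terminal_rate > 0)) {
    problems <- c(problems, "terminal_scale and terminal_rate must be > 0")
  }
  if (length(problems)) {
    abort(paste0("Invalid reward parameters:\n",
                 paste("-", problems, collapse = "\n")))
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
         terminal_scale = terminal_scale, terminal_rate = terminal_rate),
    class = "aware_reward_params"
  )
}

#' @export
print.aware_reward_params <- function(x, ...) {
  cat(sprintf(
    "<aware_reward_params> alpha %.3g, beta %.3g, gamma (%s), delta %.3g, terminal %.3g @ rate %.3g\n",
    x$alpha, x$beta, paste(signif(x$gamma, 3), collapse = ", "),
    x$delta, x$terminal_scale, x$terminal_rate
  ))
  invisible(x)
}

#' Stage reward
#'
#' `r(s, u) = alpha * s - beta * u`.
#'
#' @param s Awareness level(s).
#' @param u Decision value(s).
#' @param params A [reward_params()] object.
#' @return Stage reward value(s).
#' @examples
#' stage_reward(0.2, 0.6, reward_params(alpha = 1, beta = 1.5))
#' @export
stage_reward <- function(s, u, params = reward_params()) {
  params$alpha * s - params$beta * u
}

#' Terminal reward
#'
#' Normalised exponential in the final state: 0 at `s = 0`,
#' `terminal_scale` at `s = 1`, strictly increasing in between.
#'
#' @inheritParams stage_reward
#' @return Terminal reward value(s).
#' @export
terminal_reward <- function(s, params = reward_params()) {
  k <- params$terminal_rate
  params$terminal_scale * expm1(k * s) / expm1(k)
}

#' Emotion profile
#'
#' When emotions are enabled, the constant future weight `delta` is replaced
#' by a state- and time-dependent factor `delta(s) * t / T` with
#' `delta(s) = 1 - c * exp(-k_e * s)`: negative at low awareness (immediate
#' gratification dominates and discounting the future becomes harmful) and
#' close to 1 at high awareness (present and future weigh the same).
#'
#' @param enabled Logical; use the emotional discount factor?
#' @param c Depth of the low-awareness penalty (default 1.5, making
#'   `delta(s)` negative for `s` below about 0.1).
#' @param k_e Recovery rate towards 1 (default 4).
#' @return An object of class `aware_emotion_profile`.
#' @export
emotion_profile <- function(enabled = FALSE, c = 1.5, k_e = 4) {
  if (c < 0 || k_e <= 0) {
    abort("emotion profile requires c >= 0 and k_e > 0.")
  }
  structure(list(enabled = isTRUE(enabled), c = c, k_e = k_e),
            class = "aware_emotion_profile")
}

#' @export
print.aware_emotion_profile <- function(x, ...) {
  cat(sprintf("<aware_emotion_profile> %s, c %.3g, k_e %.3g\n",
              if (x$enabled) "enabled" else "disabled", x$c, x$k_e))
  invisible(x)
}

#' State-dependent discount multiplier
#'
#' `emotion_delta(s) = 1 - c * exp(-k_e * s)`, strictly increasing in `s`.
#'
#' @param s Awareness level(s).
#' @param profile An [emotion_profile()] object.
#' @return Discount multiplier value(s).
#' @examples
#' emotion_delta(c(0.01, 0.99)) # negative at low awareness, near 1 at high
#' @export
emotion_delta <- function(s, profile = emotion_profile(TRUE)) {
  1 - profile$c * exp(-profile$k_e * s)
}

#' Effective future-reward weight
#'
#' The weight applied to the expected future value inside a backup at stage
#' `t`. With emotions disabled it is the constant `delta`; with emotions
#' enabled it is `emotion_delta(s) * t / T`, growing linearly from 0 at the
#' first epoch to (approximately) `emotion_delta(s)` at the horizon.
#'
#' @inheritParams emotion_delta
#' @param t Decision epoch in `0:T`.
#' @param T_horizon Horizon length (> 0).
#' @param params A [reward_params()] object (supplies the constant `delta`).
#' @param profile An [emotion_profile()] object.
#' @return Discount multiplier value(s).
#' @export
effective_discount <- function(s, t, T_horizon, params = reward_params(),
                               profile = emotion_profile()) {
  if (T_horizon <= 0) abort("`T_horizon` must be a positive integer.")
  if (any(t < 0 | t > T_horizon)) abort("`t` must lie in 0:T_horizon.")
  if (profile$enabled) {
    emotion_delta(s, profile) * (t / T_horizon)
  } else {
    rep_len(params$delta, max(length(s), length(t)))
  }
}
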