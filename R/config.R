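#' Experiment configuration
#'
#' Bundles every parameter of one simulation experiment: the individual's
#' reasoning propensity and decision noise, the initial state, the horizon and
#' ensemble size, the reward and discount parameters, the emotion profile, and
#' the kernel curve shape. Validation is strict and reports every violation at
#' once; `sigma`, `T_horizon` and `N` have no silent defaults because they
#' pin the study conditions of an experiment.
#'
#' @param p_r Reasoning propensity in \[0, 1\].
#' @param sigma Standard deviation of the habitual decision noise (>= 0).
#' @param s0 Initial awareness level (used when `s0_mode = "fixed"`).
#' @param s0_mode `"fixed"` (start every run at `s0`) or `"uniform"` (draw the
#'   initial state uniformly from the grid in every run).
#' @param T_horizon Number of decision epochs; decisions are made at epochs
#'   `0, ..., T_horizon - 1` and the terminal reward is collected at
#'   `T_horizon`.
#' @param N Ensemble size (number of Monte Carlo runs).
#' @param alpha,beta,gamma,delta,terminal_scale,terminal_rate Passed to
#'   [reward_params()].
#' @param emotions Logical; enable the emotional discount factor.
#' @param emotion_c,emotion_k Passed to [emotion_profile()].
#' @param shape A [curve_shape()] object (kernel calibration).
#' @param step Grid step for [state_grid()].
#' @return An object of class `aware_config`.
#' @examples
#' cfg <- aware_config(p_r = 0.6, sigma = 0.08, s0 = 0.2, T_horizon = 50, N = 100)
#' cfg
#' @export
aware_config <- function(p_r, sigma, s0 = NULL, s0_mode = c("fixed", "uniform"),
                         T_horizon, N,
                         alpha = 1, beta = 1.5, gamma = c(3, 1, 0.1),
                         delta = 0.75, terminal_scale = 10, terminal_rate = 5,
                         emotions = FALSE, emotion_c = 1.5, emotion_k = 4,
                         shape = curve_shape(), step = 0.01) {
  s0_mode <- match.arg(s0_mode)
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(p_r) && length(p_r) == 1L && p_r >= 0 && p_r <= 1,
      "`p_r` must be a single number in [0, 1]")
  chk(is.numeric(sigma) && length(sigma) == 1L && sigma >= 0,
      "`sigma` must be a single non-negative number (no default)")
  if (s0_mode == "fixed") {
    chk(is.numeric(s0) && length(s0) == 1L && s0 > 0 && s0 < 1,
        "`s0` must be a single number in (0, 1) when `s0_mode = \"fixed\"`")
  }
  chk(is.numeric(T_horizon) && length(T_horizon) == 1L && T_horizon >= 1 &&
        T_horizon == round(T_horizon),
      "`T_horizon` must be a positive integer (no default)")
  chk(is.numeric(N) && length(N) == 1L && N >= 1 && N == round(N),
      "`N` must be a positive integer (no default)")
  if (length(problems)) {
    abort(paste0("Invalid configuration:\n",
                 paste("-", problems, collapse = "\n")))
  }
  grid <- state_grid(step)
  rewards <- reward_params(alpha = alpha, beta = beta, gamma = gamma,
                           delta = delta, terminal_scale = terminal_scale,
                           terminal_rate = terminal_rate)
  emotion <- emotion_profile(enabled = emotions, c = emotion_c, k_e = emotion_k)
  cfg <- structure(
    list(
      p_r = p_r, sigma = sigma,
      s0 = if (s0_mode == "fixed") s0 else NA_real_, s0_mode = s0_mode,
      T_horizon = as.integer(T_horizon), N = as.integer(N),
      rewards = rewards, emotion = emotion, shape = shape, grid = grid
    ),
    class = "aware_config"
  )
  cfg
}

#' @export
print.aware_config <- function(x, ...) {
  cat(sprintf(
    paste0("<aware_config> p_r %.2f, sigma %.3g, s0 %s (%s), T %d, N %d,\n",
           "  alpha %.3g, beta %.3g, gamma (%s), delta %.3g, emotions %s\n",
           "  hash %s\n"),
    x$p_r, x$sigma,
    if (x$s0_mode == "fixed") sprintf("%.2f", x$s0) else "-", x$s0_mode,
    x$T_horizon, x$N,
    x$rewards$alpha, x$rewards$beta,
    paste(signif(x$rewards$gamma, 3), collapse = ", "),
    x$rewards$delta,
    if (x$emotion$enabled) "on" else "off",
    config_hash(x)
  ))
  invisible(x)
}

#' Stable hash of a configuration
#'
#' Used to stamp every output with the configuration that produced it.
#'
#' @param config An [aware_config()] object.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass_deep(config))
}

# strip classes/attributes so the hash depends only on parameter values
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unname(x)
}

preset_table <- function() {
  base67 <- list(alpha = 10, beta = 20, gamma = c(3.7, 1, 0.01), sigma = 0.08,
                 T_horizon = 300, N = 3000, emotions = TRUE)
  list(
    # moderately analytical individual, emotions off; short horizon
    fig6 = list(p_r = 0.6, sigma = 0.08, s0 = 0.2, T_horizon = 100, N = 3000,
                alpha = 1, beta = 1.5, gamma = c(3, 1, 0.1), delta = 0.75,
                emotions = FALSE),
    # analytical individual (p_r = 0.8) with emotions
    fig7a = c(list(p_r = 0.8, s0 = 0.2), base67),
    fig7b = c(list(p_r = 0.8, s0 = 0.2), base67),
    fig7c = c(list(p_r = 0.8, s0 = 0.9), base67),
    # intuitive individual (p_r = 0.2) with emotions
    fig8a = c(list(p_r = 0.2, s0 = 0.2), base67),
    fig8b = c(list(p_r = 0.2, s0 = 0.2), base67),
    fig8c = c(list(p_r = 0.2, s0 = 0.9), base67)
  )
}

#' Named experiment presets
#'
#' Bind the printed parameter sets of the reference simulation experiments:
#' `"fig6"` (moderately analytical individual, emotions off, T = 100),
#' `"fig7a"`/`"fig7b"` (analytical individual, emotions on, low start),
#' `"fig7c"` (analytical, emotions on, high start), `"fig8a"`/`"fig8b"`
#' (intuitive individual, emotions on, low start) and `"fig8c"` (intuitive,
#' emotions on, high start). All emotion presets use T = 300.
#'
#' @param name Preset name; see `preset_names()` for the list.
#' @param ... Overrides passed on to [aware_config()] (e.g. a smaller `N`).
#' @return An [aware_config()] object.
#' @examples
#' aware_preset("fig6", N = 50)
#' @export
aware_preset <- function(name, ...) {
  presets <- preset_table()
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown preset '%s'. Available: %s.",
                  name, paste(names(presets), collapse = ", ")))
  }
  args <- modifyList(presets[[name]], list(...))
  do.call(aware_config, args)
}

#' @rdname aware_preset
#' @export
preset_names <- function() names(preset_table())

#' Read and write configurations
#'
#' Configurations serialise losslessly to a human-readable YAML file.
#'
#' @param config An [aware_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   an [aware_config()] object.
#' @export
write_config <- function(config, path) {
  x <- list(
    p_r = config$p_r, sigma = config$sigma,
    s0 = if (config$s0_mode == "fixed") config$s0 else NULL,
    s0_mode = config$s0_mode,
    T_horizon = config$T_horizon, N = config$N,
    alpha = config$rewards$alpha, beta = config$rewards$beta,
    gamma = config$rewards$gamma, delta = config$rewards$delta,
    terminal_scale = config$rewards$terminal_scale,
    terminal_rate = config$rewards$terminal_rate,
    emotions = config$emotion$enabled,
    emotion_c = config$emotion$c, emotion_k = config$emotion$k_e,
    shape = unclass(config$shape),
    step = config$grid$step
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  x <- yaml::read_yaml(path)
  known <- c("p_r", "sigma", "s0", "s0_mode", "T_horizon", "N", "alpha",
             "beta", "gamma", "delta", "terminal_scale", "terminal_rate",
             "emotions", "emotion_c", "emotion_k", "shape", "step")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(x$gamma)) x$gamma <- as.numeric(unlist(x$gamma))
  if (!is.null(x$shape)) x$shape <- do.call(curve_shape, x$shape)
  do.call(aware_config, x)
}
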